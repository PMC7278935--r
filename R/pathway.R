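#' Build the reference LC-/VLC-PUFA biosynthesis pathway graph
#'
#' Encodes the teleost LC-PUFA pathway from the C18 precursors
#' (18:3n-3 and 18:2n-6) through Delta-6/Delta-5 desaturations and
#' elongations, plus the Elovl4-driven very long-chain elongation
#' families up to a C36 ceiling. Two alternative DHA routes are switched
#' by the species profile: the Sprecher route (elongation of 22:5n-3 to
#' 24:5n-3, Delta-6 desaturation to 24:6n-3, then one round of partial
#' beta-oxidation back to 22:6n-3, with the n-6 mirror) and the direct
#' Delta-4 desaturation of 22:5n-3. Gilthead seabream operates the
#' Sprecher route; Senegalese sole the Delta-4 route. Both species lack
#' elovl2, so `has_elovl2` must be `FALSE` (reserved for other taxa).
#'
#' @param has_sprecher_delta6 logical; include the Sprecher Delta-6 /
#'   beta-oxidation shunt.
#' @param has_delta4 logical; include the direct Delta-4 desaturations.
#' @param has_elovl2 logical; must be `FALSE` (not modeled).
#' @param max_carbons chain-length ceiling for elongation edges (36).
#' @param vlc_seeds shorthand strings seeding the very long-chain
#'   elongation families; defaults to the substrates assayed in the
#'   yeast experiments.
#' @return A tibble of reactions with columns `substrate`, `kind`
#'   (`elongation`, `desaturation`, `beta_oxidation`), `label`, `product`,
#'   of class `pathway_graph`; the species profile is kept as an
#'   attribute.
#' @export
#' @examples
#' g <- build_reference_pathway(has_sprecher_delta6 = TRUE, has_delta4 = FALSE)
#' dplyr::filter(g, kind == "beta_oxidation")
build_reference_pathway <- function(has_sprecher_delta6 = TRUE,
                                    has_delta4 = FALSE,
                                    has_elovl2 = FALSE,
                                    max_carbons = 36L,
                                    vlc_seeds = c("18:4n-3", "18:3n-6",
                                                  "20:5n-3", "20:4n-6",
                                                  "22:5n-3", "22:4n-6",
                                                  "22:6n-3")) {
  if (isTRUE(has_elovl2)) {
    stop_vlcfa("elovl2 is absent from the genomes modeled here; has_elovl2 must be FALSE",
               "vlcfa_bad_argument")
  }
  edge <- function(substrate, kind, label, product) {
    tibble(substrate = substrate, kind = kind, label = label, product = product)
  }
  desat <- function(s, label) {
    p <- parse_fa(s)
    edge(s, "desaturation", label,
         format_fa(p$carbons, p$double_bonds + 1L, p$series))
  }
  elong_label <- function(product_carbons) {
    ifelse(product_carbons <= 22L, "Elovl5", "Elovl4")
  }
  elong_chain <- function(from) {
    prods <- product_series(from, max_carbons)
    if (length(prods) == 0) return(NULL)
    subs <- c(from, head(prods, -1))
    edge(subs, "elongation", elong_label(parse_fa(prods)$carbons), prods)
  }

  edges <- bind_rows(
    # n-3 branch to EPA
    desat("18:3n-3", "Δ6"),
    desat("20:4n-3", "Δ5"),
    # n-6 branch to ARA
    desat("18:2n-6", "Δ6"),
    desat("20:3n-6", "Δ5"),
    # elongation families up to the VLC ceiling
    bind_rows(lapply(vlc_seeds, elong_chain))
  )
  if (isTRUE(has_sprecher_delta6)) {
    edges <- bind_rows(
      edges,
      desat("24:5n-3", "Δ6"),
      edge("24:6n-3", "beta_oxidation", "β-ox", "22:6n-3"),
      desat("24:4n-6", "Δ6"),
      edge("24:5n-6", "beta_oxidation", "β-ox", "22:5n-6")
    )
  }
  if (isTRUE(has_delta4)) {
    edges <- bind_rows(edges,
                       desat("22:5n-3", "Δ4"),
                       desat("22:4n-6", "Δ4"))
  }
  edges <- distinct(edges, .data$substrate, .data$product, .keep_all = TRUE)
  validate_pathway_edges(edges)
  structure(edges,
            class = c("pathway_graph", class(edges)),
            species_profile = list(has_sprecher_delta6 = isTRUE(has_sprecher_delta6),
                                   has_delta4 = isTRUE(has_delta4),
                                   has_elovl2 = FALSE))
}

# internal: every edge must satisfy its reaction kind's arithmetic
validate_pathway_edges <- function(edges) {
  s <- parse_fa(edges$substrate)
  p <- parse_fa(edges$product)
  ok <- rep(TRUE, nrow(edges))
  el <- edges$kind == "elongation"
  de <- edges$kind == "desaturation"
  bo <- edges$kind == "beta_oxidation"
  ok[el] <- p$carbons[el] == s$carbons[el] + 2L &
    p$double_bonds[el] == s$double_bonds[el] & p$series[el] == s$series[el]
  ok[de] <- p$double_bonds[de] == s$double_bonds[de] + 1L &
    p$carbons[de] == s$carbons[de] & p$series[de] == s$series[de]
  ok[bo] <- p$carbons[bo] == s$carbons[bo] - 2L &
    p$double_bonds[bo] == s$double_bonds[bo] & p$series[bo] == s$series[bo]
  if (!all(ok)) {
    i <- which(!ok)[1]
    stop_vlcfa(sprintf("reaction %s -> %s violates %s arithmetic",
                       edges$substrate[i], edges$product[i], edges$kind[i]),
               "vlcfa_invalid_reaction")
  }
  invisible(edges)
}

#' Nodes of a pathway graph
#'
#' @param graph a `pathway_graph` tibble.
#' @return character vector of fatty-acid shorthand node names.
#' @export
pathway_nodes <- function(graph) {
  sort(unique(c(graph$substrate, graph$product)))
}

# internal: pathway tibble -> igraph with edge attributes
pathway_igraph <- function(graph) {
  igraph::graph_from_data_frame(
    data.frame(from = graph$substrate, to = graph$product,
               kind = graph$kind, label = graph$label),
    directed = TRUE
  )
}

#' Enumerate biosynthetic routes between two fatty acids
#'
#' All simple (no node revisited) reaction paths from `from` to `to` with
#' at most `max_steps` reactions, in deterministic order (lexicographic by
#' the concatenated edge labels). Asking for a route from a node to itself
#' yields a single empty route.
#'
#' @param graph a `pathway_graph` tibble from [build_reference_pathway()].
#' @param from,to shorthand strings; both must be nodes of the graph.
#' @param max_steps maximum number of reactions per route (default 12).
#' @return A list of tibbles, one per route, each with the edge columns
#'   `substrate`, `kind`, `label`, `product` in traversal order.
#' @export
#' @examples
#' g <- build_reference_pathway(has_sprecher_delta6 = TRUE)
#' enumerate_routes(g, "22:5n-3", "22:6n-3")
enumerate_routes <- function(graph, from, to, max_steps = 12L) {
  nodes <- pathway_nodes(graph)
  missing <- setdiff(c(from, to), nodes)
  if (length(missing) > 0) {
    stop_vlcfa(sprintf("fatty acid '%s' is not a node of the pathway graph",
                       missing[1]), "vlcfa_lookup_error")
  }
  empty_route <- graph[0, c("substrate", "kind", "label", "product")]
  if (identical(from, to)) {
    return(list(as_tibble(empty_route)))
  }
  ig <- pathway_igraph(graph)
  paths <- igraph::all_simple_paths(ig, from = from, to = to,
                                    mode = "out", cutoff = max_steps)
  routes <- lapply(paths, function(vp) {
    nm <- names(vp)
    hops <- tibble(substrate = head(nm, -1), product = tail(nm, -1))
    left_join(hops, graph, by = c("substrate", "product")) |>
      select("substrate", "kind", "label", "product")
  })
  if (length(routes) > 1) {
    # locale-independent lexicographic order on the label sequence
    # (labels contain non-ASCII enzyme symbols, so sort by codepoints)
    key <- vapply(routes, function(r) {
      paste(sprintf("%06x", utf8ToInt(enc2utf8(paste(r$label, collapse = "")))),
            collapse = "-")
    }, "")
    routes <- routes[order(key, method = "radix")]
  }
  routes
}
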