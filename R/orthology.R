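#' Cap ortholog degrees
#'
#' Removes worm genes with more than `max_orthologs` mammalian partners
#' (with all their edges), then mammalian genes with more than
#' `max_orthologs` worm partners. Exactly `max_orthologs` partners is
#' retained (inclusive cap). With `iterate = TRUE` the two passes repeat
#' until degrees stabilise.
#'
#' @param map data frame with columns `worm` and `mammal` (bipartite edge
#'   list; duplicate edges are collapsed).
#' @param max_orthologs inclusive degree cap (default 10).
#' @param iterate re-check degrees after removals (default off).
#' @return the filtered edge list.
#' @export
filter_degree <- function(map, max_orthologs = 10, iterate = FALSE) {
  map <- unique(map[, c("worm", "mammal")])
  repeat {
    deg_w <- table(map$worm)
    map2 <- map[deg_w[map$worm] <= max_orthologs, , drop = FALSE]
    deg_m <- table(map2$mammal)
    map2 <- map2[deg_m[map2$mammal] <= max_orthologs, , drop = FALSE]
    if (!iterate || nrow(map2) == nrow(map)) {
      rownames(map2) <- NULL
      return(map2)
    }
    map <- map2
  }
}

#' Transitively merged ortholog groups
#'
#' Treats orthology as a transitive property: worm genes that share any
#' mammalian ortholog are merged, and mammalian genes that share any worm
#' ortholog likewise, i.e. groups are the connected components of the
#' bipartite orthology graph.
#'
#' @param map a (degree-filtered) edge list with `worm`, `mammal`.
#' @return list of class `ortholog_groups`; each element has
#'   `worm_members`, `mammal_members`, `group_id`.
#' @export
build_groups <- function(map) {
  if (nrow(map) == 0) return(structure(list(), class = "ortholog_groups"))
  wn <- paste0("w:", map$worm)
  mn <- paste0("m:", map$mammal)
  g <- igraph::graph_from_edgelist(cbind(wn, mn), directed = FALSE)
  comp <- igraph::components(g)
  vn <- igraph::V(g)$name
  groups <- lapply(seq_len(comp$no), function(k) {
    members <- vn[comp$membership == k]
    list(group_id = sprintf("OG%04d", k),
         worm_members = sort(sub("^w:", "", members[startsWith(members, "w:")])),
         mammal_members = sort(sub("^m:", "", members[startsWith(members, "m:")])))
  })
  structure(groups, class = "ortholog_groups")
}

#' Cross-species PUF target overlap over ortholog groups
#'
#' A group is worm-targeted if any of its worm members is in
#' `worm_targets`; it is shared if additionally any mammalian member is in
#' `mammal_targets`. The shared fraction is shared / worm-targeted.
#' Target identifiers absent from every group are reported as unmatched,
#' not silently dropped.
#'
#' @param groups an `ortholog_groups` list.
#' @param worm_targets,mammal_targets character vectors of gene ids.
#' @return list of class `overlap_report`: `shared_fraction` (NA when no
#'   group is worm-targeted), `n_worm_targeted`, `n_shared`,
#'   `unmatched_worm`, `unmatched_mammal`, and a per-group `table`.
#' @export
compute_overlap <- function(groups, worm_targets, mammal_targets) {
  worm_targeted <- vapply(groups, function(g)
    any(g$worm_members %in% worm_targets), logical(1))
  shared <- worm_targeted & vapply(groups, function(g)
    any(g$mammal_members %in% mammal_targets), logical(1))
  all_worm <- unique(unlist(lapply(groups, `[[`, "worm_members")))
  all_mam <- unique(unlist(lapply(groups, `[[`, "mammal_members")))
  tab <- data.frame(
    group_id = vapply(groups, `[[`, character(1), "group_id"),
    n_worm = vapply(groups, function(g) length(g$worm_members), integer(1)),
    n_mammal = vapply(groups, function(g) length(g$mammal_members), integer(1)),
    worm_targeted = worm_targeted, shared = shared,
    stringsAsFactors = FALSE)
  structure(list(
    shared_fraction = if (sum(worm_targeted) == 0) NA_real_
                      else sum(shared) / sum(worm_targeted),
    n_worm_targeted = sum(worm_targeted),
    n_shared = sum(shared),
    unmatched_worm = setdiff(worm_targets, all_worm),
    unmatched_mammal = setdiff(mammal_targets, all_mam),
    table = tab), class = "overlap_report")
}

#' Simulate a synthetic worm-mammal ortholog map
#'
#' Builds a random bipartite orthology map over the synthetic gene
#' universe, plus a synthetic mammalian PUF target list enriched for the
#' orthologs of a chosen set of worm genes (e.g. the gender-neutral
#' blocks), for exercising the cross-species overlap stage on fixtures.
#'
#' @param worm_genes worm gene universe.
#' @param enriched_worm worm genes whose orthologs are made likely PUF
#'   targets.
#' @param frac_with_ortholog fraction of worm genes given >= 1 ortholog.
#' @param p_target_enriched,p_target_background probability that a mammal
#'   ortholog is a PUF target for enriched vs other worm genes.
#' @param seed RNG seed.
#' @return list: `map` (edge list), `mammal_targets`.
#' @export
simulate_ortholog_map <- function(worm_genes, enriched_worm = character(0),
                                  frac_with_ortholog = 0.6,
                                  p_target_enriched = 0.7,
                                  p_target_background = 0.15,
                                  seed = 1L) {
  set.seed(seed)
  has <- stats::runif(length(worm_genes)) < frac_with_ortholog
  edges <- list(); mam_target <- character(0)
  m_id <- 0L
  for (i in which(has)) {
    k <- sample(1:3, 1L, prob = c(0.7, 0.2, 0.1))
    mams <- sprintf("HS%05d", m_id + seq_len(k)); m_id <- m_id + k
    edges[[length(edges) + 1L]] <- data.frame(worm = worm_genes[i],
                                              mammal = mams,
                                              stringsAsFactors = FALSE)
    p <- if (worm_genes[i] %in% enriched_worm) p_target_enriched
         else p_target_background
    mam_target <- c(mam_target, mams[stats::runif(k) < p])
  }
  map <- do.call(rbind, edges)
  # occasional shared orthologs create multi-gene groups
  n_extra <- max(1L, nrow(map) %/% 20L)
  extra <- data.frame(worm = sample(map$worm, n_extra, replace = TRUE),
                      mammal = sample(map$mammal, n_extra, replace = TRUE),
                      stringsAsFactors = FALSE)
  list(map = unique(rbind(map, extra)), mammal_targets = unique(mam_target))
}
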