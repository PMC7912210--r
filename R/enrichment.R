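#' Gene-set collection for over-representation analysis
#'
#' @param sets Named list of character vectors (set id -> member genes).
#'   Optionally each element may carry a `name` attribute; otherwise the id
#'   doubles as the display name.
#' @param universe Character vector of background genes; defaults to the
#'   union of all set members. Members outside the universe are dropped and
#'   empty sets removed.
#' @param names Optional character vector of display names, same length as
#'   `sets`.
#' @return A `methdx_gsc` list with elements `sets`, `names`, `universe`.
#' @export
gene_set_collection <- function(sets, universe = NULL, names = NULL) {
  if (length(sets) == 0 || is.null(base::names(sets))) {
    stop_methdx("`sets` must be a non-empty named list.", "methdx_error_config")
  }
  if (is.null(universe)) universe <- unique(unlist(sets, use.names = FALSE))
  universe <- unique(as.character(universe))
  if (length(universe) == 0) {
    stop_methdx("`universe` is empty.", "methdx_error_empty")
  }
  display <- names %||% base::names(sets)
  restricted <- purrr::map(sets, function(g) unique(intersect(as.character(g), universe)))
  keep <- lengths(restricted) > 0
  if (!all(keep)) {
    rlang::inform(sprintf("dropping %d empty gene set(s) after universe restriction.",
                          sum(!keep)))
  }
  structure(list(sets = restricted[keep], names = display[keep], universe = universe),
            class = "methdx_gsc")
}

#' Read a GMT gene-set file
#'
#' One set per line: id, description, then member genes, tab-separated.
#'
#' @param path Path to the GMT file.
#' @param universe Optional background gene vector; defaults to the union
#'   of all members.
#' @return A [gene_set_collection()] object.
#' @export
read_gmt <- function(path, universe = NULL) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop_methdx("GMT file is empty.", "methdx_error_empty")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    stop_methdx(sprintf("%d GMT line(s) have fewer than 3 fields.", sum(bad)),
                "methdx_error_config")
  }
  ids <- purrr::map_chr(parts, 1)
  descs <- purrr::map_chr(parts, 2)
  members <- purrr::map(parts, function(p) p[-(1:2)])
  names(members) <- ids
  gene_set_collection(members, universe = universe, names = descs)
}

#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query set overlaps it more than
#' expected by chance: p = P(X >= k) for X hypergeometric with population
#' size |universe|, |set| successes and |query| draws, where k is the
#' observed overlap. P-values are BH-adjusted across sets and a set is
#' flagged enriched iff adjusted p < `alpha`.
#'
#' @param query Character vector of query genes; members outside the
#'   universe are dropped with a warning.
#' @param collection A [gene_set_collection()] object.
#' @param alpha Adjusted-p cut-off (default 0.05).
#' @return Tibble with columns `set_id`, `name`, `n_set`, `n_overlap`,
#'   `p_value`, `adj_p`, `enriched`, ordered by p-value.
#' @export
ora_hypergeometric <- function(query, collection, alpha = 0.05) {
  if (!inherits(collection, "methdx_gsc")) {
    stop_methdx("`collection` must come from gene_set_collection().",
                "methdx_error_config")
  }
  universe <- collection$universe
  query <- unique(as.character(query))
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    rlang::warn(sprintf("%d query gene(s) outside the universe dropped.", length(outside)))
    query <- setdiff(query, outside)
  }
  if (length(query) == 0) {
    rlang::warn("query is empty after restriction; all p-values are 1.")
  }
  N <- length(universe)
  n_draw <- length(query)
  res <- purrr::imap_dfr(collection$sets, function(members, id) {
    K <- length(members)
    k <- length(intersect(query, members))
    # upper tail P(X >= k); phyper is P(X <= q) so shift by one
    p <- if (n_draw == 0) 1 else phyper(k - 1, K, N - K, n_draw, lower.tail = FALSE)
    tibble::tibble(set_id = id, n_set = K, n_overlap = k, p_value = min(p, 1))
  })
  res$name <- collection$names[match(res$set_id, names(collection$sets))]
  res$adj_p <- bh_adjust(res$p_value)
  res$enriched <- res$adj_p < alpha
  res |>
    dplyr::select("set_id", "name", "n_set", "n_overlap", "p_value", "adj_p", "enriched") |>
    dplyr::arrange(.data$p_value)
}
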