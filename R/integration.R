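#' Intersect differential-expression and differential-methylation calls
#'
#' Forms the four direction groups: hypo-up (hypo-methylated and
#' up-regulated), hyper-down, hyper-up and hypo-down, as exact set
#' intersections. Under negative methylation-expression coupling the first
#' two are the biologically expected biomarker candidates.
#'
#' @param up,down Character vectors of up-/down-regulated genes (disjoint).
#' @param hypo,hyper Character vectors of hypo-/hyper-methylated genes
#'   (disjoint).
#' @return A `methdx_groups` list with elements `hypo_up`, `hyper_down`,
#'   `hyper_up`, `hypo_down` (sorted character vectors).
#' @export
intersect_groups <- function(up, down, hypo, hyper) {
  if (length(intersect(up, down)) > 0) {
    stop_methdx("`up` and `down` must be disjoint.", "methdx_error_config")
  }
  if (length(intersect(hypo, hyper)) > 0) {
    stop_methdx("`hypo` and `hyper` must be disjoint.", "methdx_error_config")
  }
  structure(list(
    hypo_up = sort(intersect(hypo, up)),
    hyper_down = sort(intersect(hyper, down)),
    hyper_up = sort(intersect(hyper, up)),
    hypo_down = sort(intersect(hypo, down))
  ), class = "methdx_groups")
}

#' @export
print.methdx_groups <- function(x, ...) {
  cat(sprintf("<methdx_groups> hypo-up %d | hyper-down %d | hyper-up %d | hypo-down %d\n",
              length(x$hypo_up), length(x$hyper_down),
              length(x$hyper_up), length(x$hypo_down)))
  invisible(x)
}

#' @exportS3Method generics::tidy
tidy.methdx_groups <- function(x, ...) {
  purrr::imap_dfr(unclass(x), function(genes, grp) {
    tibble::tibble(gene = genes, group = grp)
  })
}

group_direction <- c(hypo_up = "hypo", hyper_down = "hyper",
                     hyper_up = "hyper", hypo_down = "hypo")

#' Region distribution of the four integration groups
#'
#' Counts, for each group and each of the six gene regions, how many member
#' genes have at least one differentially methylated record in that region.
#' A gene in several regions counts once in each. When `region_calls`
#' carries a `call` column the counted records are restricted to the
#' group's methylation direction (hypo for hypo-up/hypo-down, hyper
#' otherwise).
#'
#' @param groups A [intersect_groups()] result.
#' @param region_calls Tibble `gene`, `region` (optionally `call`) listing
#'   each gene's differentially methylated regions, e.g. from
#'   [region_dmg_calls()].
#' @return Tibble with one row per group and one column per region label,
#'   4 rows x 6 count columns.
#' @export
region_distribution <- function(groups, region_calls) {
  if (!inherits(groups, "methdx_groups")) {
    stop_methdx("`groups` must come from intersect_groups().", "methdx_error_config")
  }
  if (!all(c("gene", "region") %in% names(region_calls))) {
    stop_methdx("`region_calls` needs columns gene, region.", "methdx_error_config")
  }
  grouped <- unique(unlist(unclass(groups), use.names = FALSE))
  absent <- setdiff(grouped, unique(region_calls$gene))
  if (length(absent) > 0) {
    stop_methdx(sprintf("gene(s) missing from `region_calls`: %s",
                        paste(absent, collapse = ", ")),
                "methdx_error_config")
  }
  rows <- purrr::imap_dfr(unclass(groups), function(genes, grp) {
    rc <- region_calls[region_calls$gene %in% genes, , drop = FALSE]
    if ("call" %in% names(rc)) {
      rc <- rc[rc$call == group_direction[[grp]], , drop = FALSE]
    }
    counts <- purrr::map_int(region_levels(), function(r) {
      length(unique(rc$gene[rc$region == r]))
    })
    tibble::tibble(group = grp, region = region_levels(), n_genes = counts)
  })
  out <- tidyr::pivot_wider(rows, names_from = "region", values_from = "n_genes")
  out$group <- factor(out$group, levels = names(group_direction))
  out <- dplyr::arrange(out, .data$group)
  out$group <- as.character(out$group)
  structure(out, class = c("methdx_region_dist", class(out)))
}

#' Published 46 + 71 gene biomarker signature
#'
#' Loads the packaged blood biomarker signature: 46 hypo-methylated
#' up-regulated genes and 71 hyper-methylated down-regulated genes, each
#' ordered by their importance in the published expression classifier.
#' File integrity is verified against a SHA-256 manifest; `raw_symbol`
#' preserves the published spelling (including the mangled token recorded
#' as SEPT4 and dot-encoded symbols such as NKX3.2) while `symbol` is the
#' canonical gene symbol.
#'
#' @param path Directory holding the fixture files; defaults to the copies
#'   installed with the package.
#' @return List of two tibbles, `hypo_up` (46 rows) and `hyper_down`
#'   (71 rows), with columns `rank`, `symbol`, `raw_symbol`.
#' @export
load_signature <- function(path = system.file("extdata", package = "methdx")) {
  manifest_file <- file.path(path, "signature_manifest.json")
  files <- c(hypo_up = "signature_hypo_up.tsv", hyper_down = "signature_hyper_down.tsv")
  if (!file.exists(manifest_file) || !all(file.exists(file.path(path, files)))) {
    stop_methdx("signature fixture files not found.", "methdx_error_fixture")
  }
  manifest <- jsonlite::read_json(manifest_file, simplifyVector = TRUE)
  out <- purrr::imap(files, function(f, nm) {
    fp <- file.path(path, f)
    sha <- digest::digest(fp, algo = "sha256", file = TRUE)
    if (!identical(sha, manifest[[f]])) {
      stop_methdx(sprintf("checksum mismatch for %s: fixture corrupted.", f),
                  "methdx_error_fixture")
    }
    readr::read_tsv(fp, col_types = readr::cols(
      rank = readr::col_integer(),
      symbol = readr::col_character(),
      raw_symbol = readr::col_character()
    ))
  })
  out
}
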