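#' Coverage of an ontology over a raw corpus
#'
#' The fraction of raw relationships successfully normalized ("roles are
#' sufficiently detailed to capture X% of the relationships").
#'
#' @param outcome a `phare_outcome`.
#' @param raws optional: the raw list the outcome came from, for a
#'   consistency check.
#' @return fraction in `[0, 1]`.
#' @export
coverage <- function(outcome, raws = NULL) {
  stopifnot(inherits(outcome, "phare_outcome"))
  if (!is.null(raws) && length(raws) != outcome$n_input) {
    phare_error("outcome was not produced from these raw relationships",
                class = "phare_consistency_error")
  }
  if (outcome$n_input == 0) {
    phare_error("coverage is undefined on empty input",
                class = "phare_empty_error")
  }
  sum(outcome$raw_status$ok) / outcome$n_input
}

#' Reduction achieved by normalization
#'
#' Convention (the source material does not print a formula): one minus the
#' ratio of distinct normalized expressions to distinct raw expressions,
#' computed over the successfully normalized inputs only. Distinctness of a
#' raw expression is string identity of (type, subject tokens, object
#' tokens); a normalized expression is an inverse/symmetry orbit (an
#' assertion and its inverse-derived twin count once).
#'
#' @inheritParams coverage
#' @return fraction in `[0, 1]`.
#' @export
reduction <- function(outcome, raws = NULL) {
  stopifnot(inherits(outcome, "phare_outcome"))
  st <- outcome$raw_status[outcome$raw_status$ok, , drop = FALSE]
  if (!nrow(st)) {
    phare_error("reduction is undefined when nothing was normalized",
                class = "phare_empty_error")
  }
  n_in <- length(unique(st$surface))
  n_out <- length(unique(st$orbit))
  1 - n_out / n_in
}

#' Duplicate-identification histogram
#'
#' Counts equivalence classes of "similar relationships" by how many times
#' each was identified, in the bins `2 <= n < 5`, `5 <= n < 10` and
#' `n >= 10`. For a raw corpus, similarity is exact string identity of
#' (type, subject, object); for a normalization outcome, identity of the
#' normalized (role, subject, object) orbit, with multiplicity the number of
#' raw records that landed on it.
#'
#' @param x a list of `phare_raw` or a `phare_outcome`.
#' @param mode count classes per bin (default, the histogram's row
#'   semantics) or records.
#' @return named integer vector `c("2-4", "5-9", "10+")`.
#' @export
duplicate_histogram <- function(x, mode = c("classes", "records")) {
  mode <- match.arg(mode)
  if (inherits(x, "phare_outcome")) {
    mult <- table(stats::na.omit(x$raw_status$orbit))
  } else {
    keys <- vapply(x, raw_surface_key, character(1))
    mult <- table(keys)
  }
  bin <- function(lo, hi = Inf) {
    sel <- mult >= lo & mult < hi
    if (mode == "classes") sum(sel) else sum(mult[sel])
  }
  c("2-4" = bin(2, 5), "5-9" = bin(5, 10), "10+" = bin(10))
}

#' Full metrics report
#'
#' Bundles the structural and effectiveness measures used to compare
#' ontologies: entity-type/role counts, mean labels per entity type and per
#' role, reduction, coverage, and the duplicate histogram of the normalized
#' outcome.
#'
#' @param onto a `phare_ontology`.
#' @param raws the raw corpus.
#' @param outcome its normalization outcome under `onto`.
#' @return a list of class `phare_metrics`.
#' @export
metrics_report <- function(onto, raws, outcome) {
  ls <- label_stats(onto)
  structure(
    list(
      n_entity_types = ls$n_entity_types,
      n_roles = ls$n_roles,
      labels_per_entity_type = ls$labels_per_entity_type,
      labels_per_role = ls$labels_per_role,
      reduction = reduction(outcome, raws),
      coverage = coverage(outcome, raws),
      duplicate_histogram = as.list(duplicate_histogram(outcome))
    ),
    class = "phare_metrics"
  )
}

#' @export
print.phare_metrics <- function(x, ...) {
  cat("PHARE-style metrics\n")
  cat(sprintf("  entity types:            %d\n", x$n_entity_types))
  cat(sprintf("  roles:                   %d\n", x$n_roles))
  cat(sprintf("  labels per entity type:  %.2f\n", x$labels_per_entity_type))
  cat(sprintf("  labels per role:         %.2f\n", x$labels_per_role))
  cat(sprintf("  reduction:               %.1f%%\n", 100 * x$reduction))
  cat(sprintf("  coverage:                %.1f%%\n", 100 * x$coverage))
  h <- x$duplicate_histogram
  cat(sprintf("  duplicates (classes):    2<=n<5: %d, 5<=n<10: %d, n>=10: %d\n",
              h[["2-4"]], h[["5-9"]], h[["10+"]]))
  invisible(x)
}
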