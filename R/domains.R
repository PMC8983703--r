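#' Extract confident domain regions from a pLDDT profile
#'
#' Implements the confident-domain rule for predicted structure models:
#' (1) find all maximal contiguous runs of residues with pLDDT strictly
#' greater than `plddt_min` whose length is strictly greater than
#' `min_run`; (2) merge runs separated by at most `merge_gap` non-confident
#' residues, including the intervening residues regardless of their
#' confidence. Merging is applied transitively until a fixpoint, so a chain
#' of qualifying runs each separated by small gaps collapses into one
#' region. Post-merge lengths are not re-checked: each constituent run
#' already passed the length filter.
#'
#' @param profile A `zd_confidence_profile` or numeric vector on the 0-100
#'   scale.
#' @param plddt_min Confidence cutoff (default 70; the rule is strict,
#'   `> 70`).
#' @param min_run Minimum run length, strict (default 50, i.e. runs of 51+
#'   residues qualify).
#' @param merge_gap Maximum number of intervening non-confident residues
#'   that still get merged (default 5, inclusive).
#' @return Data frame with columns `start`, `end` (1-based inclusive
#'   residue indices), `n_confident`, `mean_plddt`; zero rows when no
#'   domain qualifies.
#' @export
extract_confident_domains <- function(profile, plddt_min = 70,
                                      min_run = 50, merge_gap = 5) {
  vals <- as.numeric(profile)
  if (length(vals) == 0L) stop("empty confidence profile")
  conf <- vals > plddt_min
  r <- rle(conf)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths > min_run
  regions <- cbind(start = starts[keep], end = ends[keep])
  if (nrow(regions) == 0L)
    return(data.frame(start = integer(), end = integer(),
                      n_confident = integer(), mean_plddt = numeric()))
  # transitive merge left-to-right (regions are sorted and disjoint)
  merged <- regions[1, , drop = FALSE]
  if (nrow(regions) > 1) {
    for (i in 2:nrow(regions)) {
      gap <- regions[i, "start"] - merged[nrow(merged), "end"] - 1L
      if (gap <= merge_gap) {
        merged[nrow(merged), "end"] <- regions[i, "end"]
      } else {
        merged <- rbind(merged, regions[i, , drop = FALSE])
      }
    }
  }
  data.frame(
    start = as.integer(merged[, "start"]),
    end = as.integer(merged[, "end"]),
    n_confident = vapply(seq_len(nrow(merged)), function(i)
      sum(conf[merged[i, "start"]:merged[i, "end"]]), integer(1)),
    mean_plddt = vapply(seq_len(nrow(merged)), function(i)
      mean(vals[merged[i, "start"]:merged[i, "end"]]), numeric(1)))
}

#' Aggregate domain statistics over a collection of models
#'
#' @param profiles List of confidence profiles (numeric vectors on the
#'   0-100 scale).
#' @param ... Passed to [extract_confident_domains()].
#' @return List with `n_domains`, `residue_fraction` (residues inside
#'   domains over total residues) and `n_models_without_domains`.
#' @export
domain_coverage <- function(profiles, ...) {
  if (length(profiles) == 0L) stop("no profiles supplied")
  n_domains <- 0L
  in_domain <- 0
  total <- 0
  n_empty <- 0L
  for (p in profiles) {
    d <- extract_confident_domains(p, ...)
    n_domains <- n_domains + nrow(d)
    in_domain <- in_domain + sum(d$end - d$start + 1L)
    total <- total + length(p)
    if (nrow(d) == 0L) n_empty <- n_empty + 1L
  }
  list(n_domains = n_domains,
       residue_fraction = in_domain / total,
       n_models_without_domains = n_empty)
}

#' Read a two-column residue/pLDDT profile file
#'
#' Whitespace-separated `residue_index plddt` rows (header line allowed);
#' values on a 0-1 scale are rescaled to 0-100.
#'
#' @param path Input file.
#' @return A `zd_confidence_profile`.
#' @export
read_plddt_profile <- function(path) {
  first <- readLines(path, n = 1L, warn = FALSE)
  skip <- if (grepl("[A-Za-z]", first)) 1L else 0L
  tab <- read.table(path, header = FALSE, skip = skip)
  vals <- tab[[2]][order(tab[[1]])]
  if (max(vals) <= 1) vals <- vals * 100
  structure(as.numeric(vals), class = "zd_confidence_profile")
}

#' Slice per-domain structures out of a parent model
#'
#' @param s A `zd_structure`.
#' @param domains Data frame from [extract_confident_domains()] (indices
#'   refer to sequential residue positions).
#' @return List of `zd_structure`s, one per domain row.
#' @export
slice_domains <- function(s, domains) {
  stopifnot(inherits(s, "zd_structure"))
  lapply(seq_len(nrow(domains)), function(i) {
    sel <- s$atoms$residue_index >= domains$start[i] &
      s$atoms$residue_index <= domains$end[i]
    as_zd_structure(s$atoms[sel, , drop = FALSE],
                    id = sprintf("%s_dom%d_%d-%d", s$id, i,
                                 domains$start[i], domains$end[i]))
  })
}
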