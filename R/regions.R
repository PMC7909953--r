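#' Partition branch generations into three regions
#'
#' Divides the branching generations into three regions of (approximately)
#' equal summed average branch length: R1 (hilar-enriched), R2
#' (intermediate), R3 (peripheral-enriched). The optimal region size is
#' `S = sum(l_Gn) / 3`, where `l_Gn` is the average branch length of the
#' n-th generation. Generations are assigned greedily in order, closing
#' region k at the generation whose inclusion brings the cumulative sum
#' nearest to `k * S`; each region is kept nonempty. Ties go to the earlier
#' generation.
#'
#' @param l_gn numeric vector of per-generation mean branch lengths (mm), or
#'   the data frame from [lengths_by_generation()].
#' @return A `region_partition`: list with border generations `T1`, `T2`
#'   (last generation of R1 and R2), `target_size_mm` (`S`), `M`, and a
#'   `generations` data frame mapping generation to region.
#' @export
region_borders <- function(l_gn) {
  l <- as_lgn(l_gn)
  if (length(l) < 3) stop("too few generations to partition (need >= 3)")
  make_partition(l, sum(l) / 3, reference = FALSE)
}

#' Partition a second system against a reference region size
#'
#' Region borders for a second system (typically BD) using the target region
#' size `S` derived from a reference system (typically PV via
#' [region_borders()]): the second system's generations are matched against
#' its own cumulative `l_Gn` sums at `S` and `2 S`. This is why the two
#' systems' generation ranges per region generally differ. If the second
#' system's total is smaller than `S`, all generations fall in R1 with a
#' warning; if the closure would leave R3 empty, the last generation is
#' forced into R3 with a warning.
#'
#' @param l_gn_other per-generation mean lengths of the second system.
#' @param target_size_mm reference region size `S` in mm.
#' @return A `region_partition` (with the reference `S` as target size).
#' @export
apply_reference_partition <- function(l_gn_other, target_size_mm) {
  l <- as_lgn(l_gn_other)
  if (!length(l)) stop("empty generation length vector")
  if (target_size_mm <= 0) stop("target_size_mm must be positive")
  make_partition(l, target_size_mm, reference = TRUE)
}

as_lgn <- function(l_gn) {
  if (is.data.frame(l_gn)) l_gn <- l_gn$mean_curved_mm
  l <- as.numeric(l_gn)
  if (any(!is.finite(l)) || any(l <= 0))
    stop("per-generation lengths must be positive and finite")
  l
}

make_partition <- function(l, S, reference) {
  M <- length(l)
  cs <- cumsum(l)
  if (cs[M] < S) {
    warning("total generation length (", signif(cs[M], 4),
            " mm) is smaller than the reference region size; ",
            "all generations assigned to R1")
    region <- rep(1L, M)
    T1 <- M; T2 <- M
  } else if (M < 3) {
    # degenerate partition: assign by where each generation starts
    cs_prev <- c(0, cs[-M])
    region <- pmin(1L + (cs_prev >= S - 1e-12) + (cs_prev >= 2 * S - 1e-12),
                   3L)
    T1 <- max(1L, sum(region == 1))
    T2 <- T1 + sum(region == 2)
    warning("fewer than three generations; region(s) left empty")
  } else {
    T1 <- which.min(abs(cs[seq_len(M - 2)] - S))
    rng <- (T1 + 1):(M - 1)
    T2 <- rng[which.min(abs(cs[rng] - 2 * S))]
    # warn when the nonemptiness constraint overrode the free optimum
    free_T2 <- which.min(abs(cs - 2 * S))
    if (free_T2 > M - 1)
      warning("closure at 2S would leave R3 empty; ",
              "last generation forced into R3")
    region <- 1L + (seq_len(M) > T1) + (seq_len(M) > T2)
  }
  structure(
    list(T1 = T1, T2 = T2, target_size_mm = S, M = M,
         generations = data.frame(generation = seq_len(M),
                                  region = paste0("R", region),
                                  l_gn_mm = l),
         reference = reference),
    class = "region_partition")
}

#' @export
print.region_partition <- function(x, ...) {
  rng <- function(r) {
    g <- x$generations$generation[x$generations$region == r]
    if (!length(g)) "-" else paste0(min(g), "-", max(g))
  }
  cat(sprintf("<region_partition> S = %.3f mm | R1: %s  R2: %s  R3: %s\n",
              x$target_size_mm, rng("R1"), rng("R2"), rng("R3")))
  invisible(x)
}

#' Per-region branch summaries
#'
#' Fills a [region_borders()] partition with per-region summaries: region
#' size (sum of the per-generation average branch lengths `l_Gn` within the
#' region), mean branch length over the region's branches, branch count,
#' and the percentage of all branches falling in the region.
#'
#' @param table a `branch_table` from [assign_generations()].
#' @param partition a `region_partition`.
#' @param l_gn optional precomputed [lengths_by_generation()] table; by
#'   default derived from `table`.
#' @return The partition with a `summary` data frame added.
#' @export
region_summaries <- function(table, partition, l_gn = NULL) {
  stopifnot(inherits(table, "branch_table"),
            inherits(partition, "region_partition"))
  if (is.null(l_gn)) l_gn <- lengths_by_generation(table)
  gen2region <- partition$generations$region[
    match(l_gn$generation, partition$generations$generation)]
  if (anyNA(gen2region))
    stop("branch table contains generations outside the partition")
  breg <- partition$generations$region[
    match(table$generation, partition$generations$generation)]
  total <- nrow(table)
  summary <- do.call(rbind, lapply(c("R1", "R2", "R3"), function(r) {
    gens <- l_gn$generation[gen2region == r]
    v <- table$curved_mm[breg == r]
    data.frame(
      region = r,
      generations = if (length(gens)) paste0(min(gens), "-", max(gens)) else "",
      size_mm = sum(l_gn$mean_curved_mm[gen2region == r]),
      mean_branch_length_mm = if (length(v)) mean(v) else NA_real_,
      branch_count = length(v),
      branch_percent = 100 * length(v) / total)
  }))
  rownames(summary) <- NULL
  partition$summary <- summary
  partition
}

#' Per-region tortuosity
#'
#' Pools the branches of each region and reports
#' `tortuosity_percent(sum(curved), sum(chord))` per region. With all
#' branches in a single region this equals the whole-system value.
#'
#' @param table a `branch_table`.
#' @param partition a `region_partition`.
#' @return Named numeric vector (`R1`, `R2`, `R3`), NA for empty regions.
#' @export
tortuosity_by_region <- function(table, partition) {
  stopifnot(inherits(table, "branch_table"),
            inherits(partition, "region_partition"))
  breg <- partition$generations$region[
    match(table$generation, partition$generations$generation)]
  vapply(setNames(c("R1", "R2", "R3"), c("R1", "R2", "R3")), function(r) {
    sel <- !is.na(breg) & breg == r
    if (!any(sel)) return(NA_real_)
    tortuosity_percent(sum(table$curved_mm[sel]), sum(table$chord_mm[sel]))
  }, numeric(1))
}
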