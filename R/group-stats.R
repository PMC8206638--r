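.group_result <- function(test_name, statistic = NA_real_, df = NA_real_,
                          p_value = NA_real_, effect_size = NA_real_,
                          degenerate = FALSE, extra = list()) {
  structure(c(list(test_name = test_name, statistic = statistic, df = df,
                   p_value = p_value, effect_size = effect_size,
                   degenerate = degenerate), extra),
            class = "group_test_result")
}

#' @export
print.group_test_result <- function(x, ...) {
  cat("<", x$test_name, "> ", sep = "")
  if (x$degenerate) {
    cat("degenerate (test undefined on this input)\n")
  } else {
    cat(sprintf("statistic = %.4g", x$statistic))
    if (is.finite(x$df)) cat(sprintf(", df = %g", x$df))
    cat(sprintf(", p = %.4g", x$p_value))
    if (is.finite(x$effect_size)) cat(sprintf(", effect = %.3g",
                                              x$effect_size))
    cat("\n")
  }
  invisible(x)
}

#' Paired-samples t test
#'
#' Two-tailed paired t test (`t = mean(d) / (sd(d)/sqrt(n))`, `df = n - 1`
#' with `d = x - y`), with the paired Cohen's d as effect size. Zero
#' difference variance makes the test undefined: a degenerate-flagged result
#' is returned instead of an error.
#'
#' @param x,y paired numeric vectors of equal length (n >= 2).
#' @return A `group_test_result`.
#' @examples
#' paired_t(c(5, 5, 5, 5, 5, 4, 4, 4, 3, 3),
#'          c(4, 5, 3, 2, 3, 3, 5, 3, 3, 2)) # t(9) = 2.74, p = 0.022
#' @export
paired_t <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  d <- x - y
  if (stats::sd(d) == 0) {
    return(.group_result("paired t", degenerate = TRUE))
  }
  tt <- stats::t.test(x, y, paired = TRUE)
  .group_result("paired t", statistic = unname(tt$statistic),
                df = unname(tt$parameter), p_value = tt$p.value,
                effect_size = cohens_d_paired(x, y))
}

#' Exact McNemar test of paired binary status change
#'
#' Exact binomial form on the discordant counts b (1 -> 0) and c (0 -> 1):
#' two-tailed `p = min(1, 2 * P(X <= min(b, c)))` for
#' `X ~ Binomial(b + c, 1/2)`. Chosen over the chi-square approximation
#' because the asymptotic version is invalid at cohort sizes of half a dozen
#' subjects; the continuity-corrected chi-square variant is available via
#' `chisq = TRUE`.
#'
#' @param status_t1,status_t2 paired logical (or 0/1) vectors.
#' @param chisq use the continuity-corrected chi-square variant instead.
#' @return A `group_test_result` with `b` and `c` in the extras; all
#'   concordant input gives p = 1 with a degenerate flag.
#' @export
mcnemar_region <- function(status_t1, status_t2, chisq = FALSE) {
  s1 <- as.logical(status_t1)
  s2 <- as.logical(status_t2)
  stopifnot(length(s1) == length(s2), length(s1) >= 1)
  b <- sum(s1 & !s2)
  cc <- sum(!s1 & s2)
  if (b + cc == 0) {
    return(.group_result("McNemar (exact)", p_value = 1, degenerate = TRUE,
                         extra = list(b = b, c = cc)))
  }
  if (chisq) {
    tab <- matrix(c(sum(s1 & s2), b, cc, sum(!s1 & !s2)), 2, 2)
    mt <- stats::mcnemar.test(tab, correct = TRUE)
    return(.group_result("McNemar (chi-square)",
                         statistic = unname(mt$statistic),
                         df = unname(mt$parameter), p_value = mt$p.value,
                         extra = list(b = b, c = cc)))
  }
  p <- min(1, 2 * stats::pbinom(min(b, cc), b + cc, 0.5))
  .group_result("McNemar (exact)", statistic = min(b, cc), df = b + cc,
                p_value = p, extra = list(b = b, c = cc))
}

# all permutations of 1..n as an n! x n integer matrix (n <= 8 in practice)
.permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  out <- matrix(0L, n * nrow(sub), n)
  row <- 1L
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[row:(row + nrow(sub) - 1L), ] <- cbind(k, matrix(rest[sub],
                                                         nrow(sub)))
    row <- row + nrow(sub)
  }
  out
}

#' Spearman rank correlation with exact small-sample p value
#'
#' rho is the Pearson correlation of (average) ranks. For n <= 8 the
#' two-tailed p value is exact, by enumerating the permutation distribution
#' of rho over all n! orderings (at n = 6 the t approximation is unreliable
#' and exactness costs only 720 permutations); for larger n the usual t
#' approximation is used.
#'
#' @param x,y numeric vectors of equal length (n >= 3).
#' @param exact force or disable exact enumeration; default `n <= 8`.
#' @return A `group_test_result` with `rho` as the statistic; zero rank
#'   variance gives a degenerate-flagged result.
#' @examples
#' spearman_test(1:6, 6:1) # rho = -1, exact p = 2/720
#' @export
spearman_test <- function(x, y, exact = NULL) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (is.null(exact)) exact <- n <= 8
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0) {
    return(.group_result("Spearman", degenerate = TRUE))
  }
  rho <- stats::cor(rx, ry)
  if (exact) {
    perm <- .permutations(n)
    a <- rx - mean(rx)
    rp <- matrix(ry[perm], nrow(perm))
    rho_perm <- as.vector(rp %*% a) / ((n - 1) * stats::sd(rx) *
                                         stats::sd(ry))
    p <- mean(abs(rho_perm) >= abs(rho) - 1e-12)
  } else {
    tstat <- rho * sqrt((n - 2) / max(1e-300, 1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), n - 2)
  }
  .group_result("Spearman", statistic = rho, df = n - 2, p_value = p,
                effect_size = rho,
                extra = list(exact = exact, n = n))
}

#' Cohen's d for paired samples
#'
#' `d = mean(x - y) / sd(x - y)`.
#'
#' @param x,y paired numeric vectors.
#' @return A single number; `NaN` when the difference SD is zero.
#' @export
cohens_d_paired <- function(x, y) {
  d <- x - y
  s <- stats::sd(d)
  if (s == 0) return(NaN)
  mean(d) / s
}

#' One-sample Cohen's d against a reference value
#'
#' `d = (mean(x) - mu0) / sd(x)`.
#'
#' @param x numeric vector.
#' @param mu0 reference value.
#' @return A single number; `NaN` when sd(x) is zero.
#' @export
cohens_d_one_sample <- function(x, mu0 = 0) {
  s <- stats::sd(x)
  if (s == 0) return(NaN)
  (mean(x) - mu0) / s
}

#' Collapse ROI-level membership to anatomical structures
#'
#' A structure (e.g. "hippocampus", collapsing its anterior/medial/posterior
#' aspects and both hemispheres) is flagged as a member if any of its
#' constituent ROIs is a member (logical OR).
#'
#' @param member_labels character vector of member ROI labels.
#' @param collapse_map data.frame with columns `roi` and `structure` mapping
#'   every ROI label to a structure label.
#' @return Named logical vector over all structures in the map.
#' @export
collapse_regions <- function(member_labels, collapse_map) {
  stopifnot(is.data.frame(collapse_map),
            all(c("roi", "structure") %in% names(collapse_map)))
  unknown <- setdiff(member_labels, collapse_map$roi)
  if (length(unknown) > 0) {
    stop("member labels missing from collapse_map: ",
         paste(unknown, collapse = ", "))
  }
  structures <- unique(collapse_map$structure)
  hit <- unique(collapse_map$structure[collapse_map$roi %in% member_labels])
  setNames(structures %in% hit, structures)
}

#' Region x timepoint membership counts across subjects
#'
#' Builds the membership table underlying the hub / rich-club distribution
#' tests: per structure and timepoint, the number of subjects for which that
#' structure was a member. Rows are kept when the count at either timepoint
#' reaches `min_count` (or when listed explicitly in `regions`).
#'
#' @param members_t1,members_t2 lists (one element per subject, same order)
#'   of member ROI label vectors at the two timepoints.
#' @param collapse_map optional ROI-to-structure map (see
#'   [collapse_regions()]); `NULL` treats every ROI as its own structure.
#' @param min_count inclusion threshold (default 3; hub tables typically
#'   use 1).
#' @param regions explicit region list overriding the `min_count` filter.
#' @param kind label, `"rich_club"` or `"hub"`.
#' @return An object of class `membership_table`: `table` (data.frame
#'   `region`, `count_t1`, `count_t2`), per-subject logical matrices
#'   `flags_t1`/`flags_t2` (restricted to the kept regions), `n_subjects`,
#'   `kind`, `min_count`.
#' @export
build_membership_table <- function(members_t1, members_t2,
                                   collapse_map = NULL, min_count = 3,
                                   regions = NULL, kind = "rich_club") {
  stopifnot(length(members_t1) == length(members_t2))
  n_sub <- length(members_t1)
  if (is.null(collapse_map)) {
    rois <- sort(unique(unlist(c(members_t1, members_t2))))
    collapse_map <- data.frame(roi = rois, structure = rois)
  }
  flag_mat <- function(members) {
    t(vapply(members, collapse_regions, collapse_map = collapse_map,
             setNames(logical(length(unique(collapse_map$structure))),
                      unique(collapse_map$structure))))
  }
  f1 <- flag_mat(members_t1)
  f2 <- flag_mat(members_t2)
  counts1 <- colSums(f1)
  counts2 <- colSums(f2)
  keep <- if (is.null(regions)) {
    names(counts1)[pmax(counts1, counts2) >= min_count]
  } else {
    missing_r <- setdiff(regions, names(counts1))
    if (length(missing_r) > 0) {
      stop("regions not in collapse_map: ", paste(missing_r, collapse = ", "))
    }
    regions
  }
  ord <- keep[order(-counts1[keep], -counts2[keep], keep)]
  structure(list(
    table = data.frame(region = ord, count_t1 = unname(counts1[ord]),
                       count_t2 = unname(counts2[ord]),
                       stringsAsFactors = FALSE),
    flags_t1 = f1[, ord, drop = FALSE],
    flags_t2 = f2[, ord, drop = FALSE],
    n_subjects = n_sub, kind = kind, min_count = min_count
  ), class = "membership_table")
}

#' @export
print.membership_table <- function(x, ...) {
  cat("<membership_table>", x$kind, "- n =", x$n_subjects,
      "subjects, min_count =", x$min_count, "\n")
  print(x$table, row.names = FALSE)
  invisible(x)
}

#' Test membership-distribution change over time
#'
#' Paired t test across regions on the subject counts (timepoint 1 minus
#' timepoint 2), plus per-region exact McNemar tests of individual status
#' change.
#'
#' @param mt a [build_membership_table()] result.
#' @return list with `paired_t` (a `group_test_result`) and `per_region`
#'   (data.frame: region, b, c, p_value).
#' @export
membership_change_tests <- function(mt) {
  stopifnot(inherits(mt, "membership_table"))
  tt <- paired_t(mt$table$count_t1, mt$table$count_t2)
  per <- lapply(mt$table$region, function(r) {
    m <- mcnemar_region(mt$flags_t1[, r], mt$flags_t2[, r])
    data.frame(region = r, b = m$b, c = m$c, p_value = m$p_value,
               stringsAsFactors = FALSE)
  })
  list(paired_t = tt, per_region = do.call(rbind, per))
}

#' Screen baseline network metrics against the drinking outcome
#'
#' Spearman rank correlation (exact p for n <= 8) of each baseline metric
#' against the scalar outcome (daily average g/kg during free access), with
#' no multiplicity correction by default; Holm-adjusted p values are added
#' when `holm = TRUE`.
#'
#' @param metrics data.frame of per-subject baseline metrics (columns =
#'   metrics; typically mean connection frequency, rich-club coefficient /
#'   nodes / minimum degree, clustering, assortativity).
#' @param outcome numeric vector, one value per subject (same order).
#' @param holm add Holm-adjusted p values.
#' @return data.frame with `metric`, `rho`, `p_value` (and `p_holm`).
#' @export
metric_outcome_screen <- function(metrics, outcome, holm = FALSE) {
  stopifnot(is.data.frame(metrics), nrow(metrics) == length(outcome))
  if (nrow(metrics) < 4) stop("need at least 4 subjects with metrics")
  rows <- lapply(names(metrics), function(m) {
    v <- metrics[[m]]
    if (!is.numeric(v) || anyNA(v)) {
      return(data.frame(metric = m, rho = NA_real_, p_value = NA_real_))
    }
    st <- spearman_test(v, outcome)
    data.frame(metric = m,
               rho = if (st$degenerate) NA_real_ else st$statistic,
               p_value = if (st$degenerate) NA_real_ else st$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (holm) out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}
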