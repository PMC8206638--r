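#' Reference tables from a longitudinal macaque free-access drinking study
#'
#' Small published summary tables shipped with the package and used by the
#' reproduction checks: per-subject daily average ethanol intake during free
#' access (g/kg), and the number of subjects (of six) for which each brain
#' structure was a hub / rich-club member at the alcohol-naive baseline and
#' after 180 days of free access.
#'
#' @param table which table: `"intake"`, `"rich_club"` or `"hub"`.
#' @return A data.frame.
#' @examples
#' reference_table("intake")
#' @export
reference_table <- function(table = c("intake", "rich_club", "hub")) {
  table <- match.arg(table)
  file <- switch(table,
    intake = "free_access_intake.tsv",
    rich_club = "rich_club_membership.tsv",
    hub = "hub_membership.tsv"
  )
  read.delim(system.file("extdata", file, package = "megnet",
                         mustWork = TRUE))
}

#' Illustrative 41-ROI atlas with structure collapse map
#'
#' A synthetic (reconstructed, not published) atlas of 41 default-mode and
#' reward-network ROIs — 20 bilateral pairs plus the midline vermis — with
#' the structure labels used to collapse hub / rich-club membership across
#' aspects and hemispheres. Intended for examples and synthetic cohorts; real
#' analyses should supply their own map.
#'
#' @return data.frame with columns `roi`, `structure`, `hemisphere`.
#' @export
roi_atlas_synthetic <- function() {
  read.delim(system.file("extdata", "roi_atlas_synthetic.tsv",
                         package = "megnet", mustWork = TRUE),
             stringsAsFactors = FALSE)
}

#' Recompute the in-package reproduction checks
#'
#' Recomputes, from the shipped reference tables and the package's own
#' statistics, the quantities that are checkable without per-subject MEG
#' data: the paired t test on the rich-club membership counts across the ten
#' listed regions, the hub count of a 41-node network under the top-10% rule,
#' and the free-access intake summary.
#'
#' @return list with `membership_shift` (a `group_test_result`),
#'   `hub_count_41`, `intake_mean`, `intake_sd` (both rounded to 1 decimal,
#'   matching the reference precision), and `intake_n`.
#' @export
reference_checks <- function() {
  rc <- reference_table("rich_club")
  tt <- paired_t(rc$baseline, rc$free_access)
  g41 <- generate_toy_graph("planted_club", n = 41, club_size = 8)
  intake <- reference_table("intake")$free_access_g_per_kg
  list(membership_shift = tt,
       hub_count_41 = length(identify_hubs(g41)),
       intake_mean = round(mean(intake), 1),
       intake_sd = round(stats::sd(intake), 1),
       intake_n = length(intake))
}
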