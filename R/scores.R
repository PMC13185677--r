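#' Embryo score classes and their aggregation
#'
#' Adults are scored for embryonic development on an ordinal scale
#' `0, 1, 2, 3, 4, 4b, 5`, from unfertilized or post-brooding tissue (0, 1)
#' through early embryos (2--4) to fully developed nauplii (4b, 5).
#' Two aggregations are used downstream: a three-way stage category for
#' visualization (`nonreproductive`, `early`, `late`) and the binary
#' `fertilized` dichotomy (scores 2--5) on which all phenology estimation
#' rests.
#'
#' @return A tibble with one row per score and columns `score`, `stage`
#'   (`"nonreproductive"`, `"early"`, `"late"`) and `fertilized` (logical).
#' @examples
#' embryo_scores()
#' @export
embryo_scores <- function() {
  tibble::tibble(
    score = c("0", "1", "2", "3", "4", "4b", "5"),
    stage = c("nonreproductive", "nonreproductive",
              "early", "early", "early", "late", "late"),
    fertilized = c(FALSE, FALSE, TRUE, TRUE, TRUE, TRUE, TRUE)
  )
}

# canonical column order for wide survey tables
score_cols <- function() paste0("s", embryo_scores()$score)

fertilized_cols <- function() paste0("s", embryo_scores()$score[embryo_scores()$fertilized])

late_cols <- function() paste0("s", embryo_scores()$score[embryo_scores()$stage == "late"])
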