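# Embedded study data: the 2x4 degrees-by-gender table, the 5x5x5
# eye-tracking table, and the twelve simulation population vectors (with the
# positions of the cells that are zeroed after data generation).

.degrees_counts <- c(933, 402, 51, 26,
                     661, 260, 44, 26)

# 5x5x5 counts, flat row-major over (person1_t, person2_t20, person2_t200);
# AOI levels: nose, mouth, right eye, left eye, none.
.eyetracking_counts <- c(
  # person1 = nose
  51, 2, 42, 46, 7,
  4, 0, 5, 3, 0,
  44, 4, 174, 39, 2,
  14, 3, 34, 36, 4,
  4, 1, 26, 11, 0,
  # person1 = mouth
  1, 0, 1, 2, 0,
  0, 0, 0, 0, 0,
  5, 0, 4, 2, 0,
  1, 0, 3, 0, 0,
  0, 0, 0, 0, 0,
  # person1 = right eye
  1006, 112, 921, 495, 91,
  81, 1, 79, 22, 2,
  1084, 109, 1909, 397, 134,
  486, 42, 419, 220, 33,
  63, 3, 151, 26, 1,
  # person1 = left eye
  34, 3, 7, 21, 1,
  8, 0, 2, 1, 0,
  23, 0, 20, 13, 3,
  6, 11, 5, 0, 0,
  0, 0, 3, 0, 0,
  # person1 = none
  28, 0, 18, 4, 7,
  0, 0, 2, 0, 0,
  22, 2, 98, 14, 1,
  5, 0, 25, 0, 0,
  2, 0, 0, 0, 0
)

.aoi_levels <- c("nose", "mouth", "right_eye", "left_eye", "none")

# Simulation populations: 2x4 cell probabilities as printed (4 decimals),
# flat row-major; star = flat indices of cells zeroed after generation.
.sim_populations <- list(
  sim_case1_phi10 = list(
    probs = c(0.1170, 0.1170, 0.1170, 0.1170, 0.1810, 0.1170, 0.1170, 0.1170),
    star = 7L, case = 1L, phi = 0.10),
  sim_case1_phi30 = list(
    probs = c(0.0787, 0.0787, 0.0787, 0.0787, 0.3706, 0.0787, 0.0787, 0.1573),
    star = 7L, case = 1L, phi = 0.30),
  sim_case1_phi50 = list(
    probs = c(0.0224, 0.0224, 0.0224, 0.0224, 0.7986, 0.0224, 0.0224, 0.0670),
    star = 7L, case = 1L, phi = 0.50),
  sim_case2_phi10 = list(
    probs = c(0.0569, 0.0569, 0.1708, 0.1708, 0.0569, 0.0569, 0.2598, 0.1710),
    star = c(5L, 6L), case = 2L, phi = 0.10),
  sim_case2_phi30 = list(
    probs = c(0.0413, 0.0413, 0.1237, 0.1237, 0.0413, 0.0413, 0.4636, 0.1238),
    star = c(5L, 6L), case = 2L, phi = 0.30),
  sim_case2_phi50 = list(
    probs = c(0.0347, 0.0347, 0.1040, 0.1040, 0.0347, 0.0347, 0.6185, 0.0347),
    star = c(5L, 6L), case = 2L, phi = 0.50),
  sim_case3_phi10 = list(
    probs = c(0.1071, 0.1071, 0.1071, 0.1071, 0.1857, 0.1501, 0.1287, 0.1071),
    star = 8L, case = 3L, phi = 0.10),
  sim_case3_phi30 = list(
    probs = c(0.0618, 0.0618, 0.0618, 0.0618, 0.4069, 0.1853, 0.0988, 0.0618),
    star = 8L, case = 3L, phi = 0.30),
  sim_case3_phi50 = list(
    probs = c(0.0075, 0.0199, 0.0199, 0.0199, 0.4979, 0.2324, 0.1992, 0.0033),
    star = 8L, case = 3L, phi = 0.50),
  sim_case4_phi10 = list(
    probs = c(0.1070, 0.1070, 0.1070, 0.1070, 0.1071, 0.1287, 0.1501, 0.1861),
    star = 5L, case = 4L, phi = 0.10),
  sim_case4_phi30 = list(
    probs = c(0.0581, 0.0581, 0.0581, 0.0581, 0.0614, 0.0988, 0.2015, 0.4059),
    star = 5L, case = 4L, phi = 0.30),
  sim_case4_phi50 = list(
    probs = c(0.0560, 0.0514, 0.0514, 0.0514, 0.0017, 0.1028, 0.2570, 0.4283),
    star = 5L, case = 4L, phi = 0.50)
)

#' Load an embedded study fixture
#'
#' `"degrees"` is the 2x4 gender-by-academic-degree count table (n = 2403);
#' `"eyetracking"` is the 5x5x5 dyadic gaze-location count table (n = 8851);
#' `"sim_case<k>_phi<10|30|50>"` are the 2x4 simulation population
#' probability vectors at the labeled Cramer's V, returned renormalized to
#' sum exactly to 1 (they are printed at 4 decimals), with the flat indices
#' of the cells zeroed after data generation in `$star_cells` and the
#' condition in `$case`/`$phi`.
#'
#' @param name fixture name.
#' @return a [contingency_table] or (for simulation populations) a
#'   [probability_vector] with `star_cells`, `case`, and `phi` fields.
#' @examples
#' load_fixture("degrees")
#' load_fixture("sim_case1_phi10")$star_cells
#' @export
load_fixture <- function(name) {
  if (identical(name, "degrees")) {
    return(contingency_table(
      .degrees_counts, dims = c(2L, 4L),
      labels = list(gender = c("female", "male"),
                    degree = c("bachelor", "master", "professional",
                               "doctorate"))))
  }
  if (identical(name, "eyetracking")) {
    return(contingency_table(
      .eyetracking_counts, dims = c(5L, 5L, 5L),
      labels = list(person1_t = .aoi_levels,
                    person2_t20 = .aoi_levels,
                    person2_t200 = .aoi_levels)))
  }
  if (name %in% names(.sim_populations)) {
    sp <- .sim_populations[[name]]
    pv <- probability_vector(sp$probs, dims = c(2L, 4L), renormalize = TRUE)
    pv$star_cells <- sp$star
    pv$case <- sp$case
    pv$phi <- sp$phi
    return(pv)
  }
  stop("unknown fixture '", name, "'; available: ",
       paste(c("degrees", "eyetracking", names(.sim_populations)),
             collapse = ", "))
}

#' List available fixtures
#' @return character vector of fixture names.
#' @export
list_fixtures <- function() {
  c("degrees", "eyetracking", names(.sim_populations))
}
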