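#' Define a blood-test-first triage cost scenario
#'
#' A triage strategy tests every patient with the plasma assay and sends
#' only those with an intermediate (between-cutoffs) result on to a
#' confirmatory test (CSF or amyloid PET). It is compared with giving every
#' patient the comparator test alone.
#'
#' @param cost_plasma,cost_csf,cost_pet Per-test costs (one currency);
#'   all must be non-negative.
#' @param p_intermediate Fraction of patients with an intermediate plasma
#'   result who require confirmatory testing, in `[0, 1]`.
#' @param confirmatory Which test intermediates receive: `"csf"` or `"pet"`.
#' @param comparator `"csf_alone"` or `"pet_alone"`.
#' @param confirm_positives Extension (off by default): also send
#'   plasma-positive patients for confirmatory testing, as required when a
#'   positive result gates treatment eligibility. Needs `p_positive`.
#' @param p_positive Fraction of plasma-positive patients; only used when
#'   `confirm_positives = TRUE`.
#' @return An object of class `cost_scenario`.
#' @export
cost_scenario <- function(cost_plasma, cost_csf, cost_pet,
                          p_intermediate,
                          confirmatory = c("csf", "pet"),
                          comparator = c("csf_alone", "pet_alone"),
                          confirm_positives = FALSE, p_positive = NA_real_) {
  confirmatory <- match.arg(confirmatory)
  comparator <- match.arg(comparator)
  if (any(c(cost_plasma, cost_csf, cost_pet) < 0)) {
    stop("costs must be non-negative", call. = FALSE)
  }
  if (p_intermediate < 0 || p_intermediate > 1) {
    stop("p_intermediate must be in [0, 1]", call. = FALSE)
  }
  if (confirm_positives && (is.na(p_positive) || p_positive < 0 ||
                            p_positive > 1 - p_intermediate)) {
    stop("confirm_positives requires p_positive in [0, 1 - p_intermediate]",
         call. = FALSE)
  }
  structure(
    list(cost_plasma = cost_plasma, cost_csf = cost_csf,
         cost_pet = cost_pet, p_intermediate = p_intermediate,
         confirmatory = confirmatory, comparator = comparator,
         confirm_positives = confirm_positives, p_positive = p_positive),
    class = "cost_scenario"
  )
}

#' Expected per-patient cost and savings of a triage strategy
#'
#' Expected strategy cost is the plasma test for everyone plus the
#' confirmatory test for the intermediate fraction (and, in the optional
#' extension, for plasma positives); the comparator cost is one comparator
#' test per patient. `savings_fraction = 1 - strategy / comparator`.
#'
#' @param scenario A [cost_scenario()].
#' @return A list: `expected_cost_strategy`, `expected_cost_comparator`,
#'   `savings_fraction`.
#' @export
#' @examples
#' sc <- cost_scenario(250, 1000, 2100, p_intermediate = 0.147)
#' triage_cost(sc)$savings_fraction # 0.603
triage_cost <- function(scenario) {
  stopifnot(inherits(scenario, "cost_scenario"))
  conf_cost <- switch(scenario$confirmatory, csf = scenario$cost_csf,
                      pet = scenario$cost_pet)
  comp_cost <- switch(scenario$comparator, csf_alone = scenario$cost_csf,
                      pet_alone = scenario$cost_pet)
  if (comp_cost <= 0) stop("comparator cost must be > 0", call. = FALSE)
  p_confirm <- scenario$p_intermediate +
    if (scenario$confirm_positives) scenario$p_positive else 0
  strategy <- scenario$cost_plasma + p_confirm * conf_cost
  list(
    expected_cost_strategy = strategy,
    expected_cost_comparator = comp_cost,
    savings_fraction = 1 - strategy / comp_cost
  )
}

#' Savings table over cost and intermediate-proportion grids
#'
#' Evaluates [triage_cost()] on the Cartesian product of plasma/CSF/PET
#' cost grids and intermediate proportions, against both comparators. The
#' pooled study intermediate proportion of 0.147 is included by default so
#' every table carries the headline scenario.
#'
#' @param cost_plasma,cost_csf,cost_pet Numeric vectors of per-test costs.
#' @param p_intermediate Numeric vector of intermediate fractions; 0.147 is
#'   appended if absent.
#' @param confirmatory Confirmatory test for intermediates.
#' @return A tibble with one row per combination and comparator:
#'   the inputs plus `expected_cost_strategy`, `expected_cost_comparator`,
#'   `savings_fraction`.
#' @export
savings_table <- function(cost_plasma, cost_csf, cost_pet,
                          p_intermediate = numeric(),
                          confirmatory = c("csf", "pet")) {
  confirmatory <- match.arg(confirmatory)
  if (!length(cost_plasma) || !length(cost_csf) || !length(cost_pet)) {
    stop("cost grids must be non-empty", call. = FALSE)
  }
  p_intermediate <- sort(unique(c(p_intermediate, 0.147)))
  grid <- expand.grid(cost_plasma = cost_plasma, cost_csf = cost_csf,
                      cost_pet = cost_pet,
                      p_intermediate = p_intermediate,
                      comparator = c("csf_alone", "pet_alone"),
                      stringsAsFactors = FALSE)
  res <- lapply(seq_len(nrow(grid)), function(i) {
    g <- grid[i, ]
    tc <- triage_cost(cost_scenario(g$cost_plasma, g$cost_csf, g$cost_pet,
                                    g$p_intermediate, confirmatory,
                                    g$comparator))
    tibble::tibble(
      cost_plasma = g$cost_plasma, cost_csf = g$cost_csf,
      cost_pet = g$cost_pet, p_intermediate = g$p_intermediate,
      confirmatory = confirmatory, comparator = g$comparator,
      expected_cost_strategy = tc$expected_cost_strategy,
      expected_cost_comparator = tc$expected_cost_comparator,
      savings_fraction = tc$savings_fraction)
  })
  dplyr::bind_rows(res)
}

#' Illustrative US cost inputs for the triage cost model
#'
#' Round per-test figures for a US setting: plasma p-tau217 $250, CSF AD
#' biomarker panel (including lumbar puncture) $1,000, amyloid PET $2,100,
#' with CSF as the confirmatory test for intermediate results. These are
#' inputs to [cost_scenario()], not estimates; regional costs should be
#' substituted.
#'
#' @return A named list of costs and the confirmatory test.
#' @export
default_us_costs <- function() {
  list(cost_plasma = 250, cost_csf = 1000, cost_pet = 2100,
       confirmatory = "csf")
}
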