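#' Relative water content from a fresh/dry/turgid weight triple
#'
#' RWC (%) = 100 * (fresh - dry) / (turgid - dry). Values outside
#' \[0, 100\] (fresh weight outside the dry-turgid interval, typically
#' turgid-weight measurement error) are returned as-is with a warning
#' rather than clamped.
#'
#' @param fresh_weight,dry_weight,turgid_weight Weights in grams;
#'   vectorized, recycled to a common length.
#' @return Numeric vector of RWC percentages.
#' @export
#' @examples
#' compute_rwc(3, 1, 5)   # 50
#' compute_rwc(5, 1, 5)   # 100
compute_rwc <- function(fresh_weight, dry_weight, turgid_weight) {
  if (any(!is.finite(fresh_weight) | !is.finite(dry_weight) |
            !is.finite(turgid_weight)))
    stop("weights must be finite", call. = FALSE)
  if (any(dry_weight <= 0))
    stop("dry_weight must be positive", call. = FALSE)
  if (any(turgid_weight <= dry_weight))
    stop("turgid_weight must exceed dry_weight (RWC undefined otherwise)",
         call. = FALSE)
  rwc <- 100 * (fresh_weight - dry_weight) / (turgid_weight - dry_weight)
  if (any(rwc < 0 | rwc > 100))
    warning("RWC outside [0, 100] for ", sum(rwc < 0 | rwc > 100),
            " record(s); fresh weight lies outside the dry-turgid interval",
            call. = FALSE)
  rwc
}

#' Wettest RWC band from which plants survive rapid desiccation
#'
#' Scans the survival records from wettest to driest and returns the
#' wettest band at and below which every band reaches the required
#' resurrection fraction; resurrection is all-or-nothing in the reference
#' experiment, hence the default `min_frac = 1`.
#'
#' @param survival Data frame with columns `rwc_band` (ordered wettest to
#'   driest), `n_plants`, `n_resurrected`.
#' @param min_frac Minimum resurrected fraction a band must reach.
#' @return The qualifying band name, or `NA_character_` if none.
#' @export
#' @examples
#' surv <- data.frame(rwc_band = c("100-80", "70-60", "50-40", "30-20", "<10"),
#'                    n_plants = 5, n_resurrected = c(0, 5, 5, 5, 5))
#' survival_threshold(surv)  # "70-60"
survival_threshold <- function(survival, min_frac = 1) {
  if (!is.data.frame(survival) || nrow(survival) == 0)
    stop("survival records are empty", call. = FALSE)
  req <- c("rwc_band", "n_plants", "n_resurrected")
  if (!all(req %in% names(survival)))
    stop("survival needs columns ", paste(req, collapse = ", "),
         call. = FALSE)
  if (any(survival$n_resurrected < 0 |
            survival$n_resurrected > survival$n_plants))
    stop("n_resurrected must lie in [0, n_plants]", call. = FALSE)
  ok <- survival$n_resurrected / survival$n_plants >= min_frac
  # suffix_ok[i]: band i and every drier band survive
  suffix_ok <- rev(cumprod(rev(ok))) > 0
  if (!any(suffix_ok)) return(NA_character_)
  as.character(survival$rwc_band[which(suffix_ok)[1]])
}

#' Evans Blue cell-death index
#'
#' Normalizes mean A600 readings against the assay controls: 0 at the
#' hydrated-negative mean (intact membranes exclude the dye), 1 at the
#' boiled-positive mean (complete staining), clipped to \[0, 1\]. The index
#' is instrument-independent, unlike raw absorbances.
#'
#' @param viability Data frame with columns `treatment` and `a600`.
#' @param positive,negative Treatment labels of the boiled and hydrated
#'   controls.
#' @return Named numeric vector: index per non-control treatment.
#' @export
#' @examples
#' v <- data.frame(treatment = c("boiled-positive", "hydrated-negative", "70-60"),
#'                 a600 = c(1.1, 0.1, 0.6))
#' cell_death_index(v)  # 70-60 -> 0.5
cell_death_index <- function(viability, positive = "boiled-positive",
                             negative = "hydrated-negative") {
  if (!all(c("treatment", "a600") %in% names(viability)))
    stop("viability needs columns treatment, a600", call. = FALSE)
  if (any(viability$a600 < 0))
    stop("a600 must be nonnegative", call. = FALSE)
  means <- tapply(viability$a600, viability$treatment, mean)
  for (ctrl in c(positive, negative))
    if (!ctrl %in% names(means))
      stop("missing control treatment '", ctrl, "'", call. = FALSE)
  lo <- means[[negative]]
  hi <- means[[positive]]
  if (hi <= lo)
    stop("degenerate controls: boiled-positive mean must exceed ",
         "hydrated-negative mean", call. = FALSE)
  treatments <- setdiff(names(means), c(positive, negative))
  idx <- pmin(1, pmax(0, (means[treatments] - lo) / (hi - lo)))
  setNames(as.numeric(idx), treatments)
}
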