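#' @keywords internal
"_PACKAGE"

## Diagnostic labels used throughout: raw pathology diagnoses and the three
## consolidated analytical groups.
DIAGNOSIS_LEVELS <- c("Normal", "Possible AD", "Probable AD", "Definite AD")
GROUP_LEVELS <- c("CON", "MCI", "AD")

#' The 19 anatomical brain regions profiled in multi-region AD cohorts
#'
#' Region labels used by default when simulating a 19-region cohort. The set
#' spans early (medial temporal), intermediate (parietal, frontal) and late
#' (basal ganglia) targets of Alzheimer pathology.
#'
#' @return Character vector of 19 region labels.
#' @export
brain_regions <- function() {
  c(
    "hippocampus", "entorhinal_cortex", "superior_parietal_lobule",
    "frontal_pole", "putamen", "nucleus_accumbens", "occipital_visual_cortex",
    "anterior_cingulate", "dorsolateral_prefrontal_cortex",
    "inferior_frontal_gyrus", "middle_temporal_gyrus", "temporal_pole",
    "caudate_nucleus", "precentral_gyrus", "superior_temporal_gyrus",
    "parahippocampal_gyrus", "amygdala", "posterior_cingulate",
    "inferior_temporal_gyrus"
  )
}

#' Consolidate diagnostic labels into analytical groups
#'
#' Maps the four-level neuropathological diagnosis onto the three analytical
#' groups used for all contrasts: Normal -> CON, Possible AD and Probable AD
#' -> MCI, Definite AD -> AD.
#'
#' @param diagnosis Character vector of diagnoses.
#' @return Character vector of groups ("CON", "MCI", "AD").
#' @export
consolidate_groups <- function(diagnosis) {
  map <- c(
    "Normal" = "CON", "Possible AD" = "MCI",
    "Probable AD" = "MCI", "Definite AD" = "AD"
  )
  bad <- setdiff(unique(diagnosis), names(map))
  if (length(bad) > 0) {
    stop("unknown diagnosis label(s): ", paste(bad, collapse = ", "))
  }
  unname(map[diagnosis])
}

softplus <- function(x) {
  ## numerically stable log(1 + exp(x))
  ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
}

softplus_inv <- function(y) {
  stopifnot(all(y > 0))
  ifelse(y > 30, y, log(expm1(y)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' Derive a stage seed from a global seed
#'
#' Deterministically fans one pipeline seed out to per-stage seeds so a whole
#' run is reproducible from a single integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return Integer seed below 2^31.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  bytes <- utf8ToInt(paste0(seed, "/", stage))
  ## polynomial rolling hash modulo a Mersenne prime; keeps everything
  ## inside exact double-precision integer arithmetic
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  as.integer(max(h, 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

check_fraction <- function(x, name, open_lower = FALSE, open_upper = FALSE) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    (if (open_lower) x > 0 else x >= 0) &&
    (if (open_upper) x < 1 else x <= 1)
  if (!ok) stop(sprintf("'%s' must be a fraction in [0,1]", name), call. = FALSE)
  invisible(x)
}

check_count <- function(x, name, min = 1) {
  ok <- is.numeric(x) && length(x) == 1 && is.finite(x) &&
    x == as.integer(x) && x >= min
  if (!ok) stop(sprintf("'%s' must be an integer >= %d", name, min), call. = FALSE)
  invisible(as.integer(x))
}
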