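#' Sequencing-requirement planning for organelle assemblies
#'
#' A plastome assembly at a target coverage needs
#' `plastome_size * target_coverage` bases of plastid reads; when plastid DNA
#' is only a fraction of total gDNA, the total sequencing requirement scales
#' by `1 / plastid_fraction`. With the field-typical numbers (160 kbp
#' plastome, 50x coverage) this gives 0.27 Gbp at a 3% plastid fraction and
#' 0.8 Gbp at 1%.
#'
#' @param plastome_size assembly size in bp (positive).
#' @param target_coverage fold coverage (default 50).
#' @param plastid_fraction proportion of total gDNA that is plastid, in
#'   (0, 1\].
#' @return `plan_params()`: a validated parameter list of class
#'   `plan_params`.
#' @export
plan_params <- function(plastome_size, target_coverage = 50,
                        plastid_fraction = 1) {
  if (plastome_size <= 0 || target_coverage <= 0 || plastid_fraction <= 0)
    stop("plastome_size, target_coverage and plastid_fraction must be positive")
  if (plastid_fraction > 1) stop("plastid_fraction must be <= 1")
  structure(list(plastome_size = plastome_size,
                 target_coverage = target_coverage,
                 plastid_fraction = plastid_fraction),
            class = "plan_params")
}

#' @param p a [plan_params()] object.
#' @rdname plan_params
#' @return `required_total_bp`: total gDNA sequencing requirement in bp.
#' @export
required_total_bp <- function(p) {
  stopifnot(inherits(p, "plan_params"))
  p$plastome_size * p$target_coverage / p$plastid_fraction
}

#' @rdname plan_params
#' @return `plastid_read_budget`: plastid bases needed at target coverage.
#' @export
plastid_read_budget <- function(p) {
  stopifnot(inherits(p, "plan_params"))
  p$plastome_size * p$target_coverage
}

#' Render base counts as Gbp
#'
#' Rounds half-up to two decimals and drops a trailing zero
#' ("0.8 Gbp", not "0.80 Gbp").
#'
#' @param bp base count.
#' @return character like `"0.27 Gbp"`.
#' @export
format_gbp <- function(bp) {
  g <- floor(bp / 1e9 * 100 + 0.5) / 100
  s <- formatC(g, format = "f", digits = 2)
  s <- sub("0$", "", s)
  paste0(s, " Gbp")
}

#' Absolute length difference between two assemblies
#'
#' Report utility, e.g. a 156,252 bp reference vs a 155,767 bp assembly
#' differ by 485 bp.
#'
#' @param a,b lengths in bp.
#' @return `abs(a - b)`.
#' @export
length_difference <- function(a, b) abs(a - b)
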