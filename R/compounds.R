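#' Compound parameter set
#'
#' Bundles the per-substance inputs of the analysis: predicted GI and
#' experimental plasma half-lives, the in-vitro dissolution time, and the
#' in-vivo plasma peak statistics (mean Cmax +/- SD at Tmax) the model is
#' validated against. All durations are minutes, concentrations ng/mL.
#'
#' @param name Compound label (e.g. `"NC"`, `"NC/HPbCD"`, `"NC/TAbCD"`).
#' @param t_half_gi Gastrointestinal half-life, minutes.
#' @param t_half_plasma Plasma (elimination) half-life, minutes.
#' @param dissolution_time Time to dissolution in acidic medium, minutes.
#' @param cmax_exp,cmax_exp_sd Experimental peak plasma concentration and its
#'   standard deviation, ng/mL (`NA` if unknown).
#' @param tmax_exp Experimental time of the plasma peak, minutes (`NA` if
#'   unknown).
#' @param display_digits Named vector `c(gi =, plasma =)` giving the number of
#'   decimals used by the x10^3 display convention of the published rate
#'   tables for this compound.
#' @param hydrophobic Logical; hydrophobic complexes get the slow-release
#'   initial-concentration adjustment in the short-range model.
#' @param hydrophobic_ref Name of the reference (free drug) compound whose GI
#'   rate defines the initial-scaling ratio; `NA` for non-hydrophobic entries.
#' @param reported Optional list of published reference values (display rates,
#'   precalculated and refined peaks, refined rates) used where the analysis
#'   conventions call for printed rounded inputs.
#'
#' @return An object of class `pk_compound`.
#' @export
pk_compound <- function(name, t_half_gi, t_half_plasma, dissolution_time,
                        cmax_exp = NA_real_, cmax_exp_sd = NA_real_,
                        tmax_exp = NA_real_,
                        display_digits = c(gi = 2, plasma = 2),
                        hydrophobic = FALSE, hydrophobic_ref = NA_character_,
                        reported = NULL) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  assert_positive(t_half_gi, "t_half_gi")
  assert_positive(t_half_plasma, "t_half_plasma")
  assert_positive(dissolution_time, "dissolution_time")
  for (f in c("cmax_exp", "cmax_exp_sd", "tmax_exp")) {
    v <- get(f)
    if (!is.na(v)) assert_positive(v, f)
  }
  dd <- display_digits
  if (is.list(dd)) dd <- unlist(dd)
  if (!all(c("gi", "plasma") %in% names(dd))) {
    stop("display_digits must name 'gi' and 'plasma' entries", call. = FALSE)
  }
  structure(
    list(
      name = name,
      t_half_gi = as.numeric(t_half_gi),
      t_half_plasma = as.numeric(t_half_plasma),
      dissolution_time = as.numeric(dissolution_time),
      cmax_exp = as.numeric(cmax_exp),
      cmax_exp_sd = as.numeric(cmax_exp_sd),
      tmax_exp = as.numeric(tmax_exp),
      display_digits = dd[c("gi", "plasma")],
      hydrophobic = isTRUE(hydrophobic),
      hydrophobic_ref = hydrophobic_ref,
      reported = reported
    ),
    class = "pk_compound"
  )
}

#' @export
print.pk_compound <- function(x, ...) {
  cat(sprintf("<pk_compound> %s\n", x$name))
  cat(sprintf("  t1/2 GI %.4g min | t1/2 plasma %.4g min | dissolution %.4g min\n",
              x$t_half_gi, x$t_half_plasma, x$dissolution_time))
  if (!is.na(x$cmax_exp)) {
    cat(sprintf("  experimental Cmax %.4g +/- %.4g ng/mL at Tmax %.4g min\n",
                x$cmax_exp, x$cmax_exp_sd, x$tmax_exp))
  }
  invisible(x)
}

#' Bundled study compounds
#'
#' Loads the three study substances — free nicardipine (NC), its hydrophilic
#' hydroxypropyl-beta-cyclodextrin complex (NC/HPbCD) and its hydrophobic
#' triacetyl-beta-cyclodextrin complex (NC/TAbCD) — with their half-lives,
#' dissolution times, in-vivo plasma peak statistics and the published
#' reference values used as printed-precision inputs downstream.
#'
#' @param path Path to a compounds config file; defaults to the bundled
#'   fixture.
#' @return Named list of [pk_compound] objects.
#' @export
study_compounds <- function(path = system.file("extdata", "compounds.yaml",
                                               package = "ncpk")) {
  read_compounds_config(path)
}
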