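#' Spectral photoacclimation indices
#'
#' Combines per-station, per-wavelength photosynthetic parameters with the
#' station light-climate records into the photoacclimation index table:
#' the Ek,440/Eavg ratio (both unit systems; values near one indicate that
#' light saturation is tuned to the average mixed-layer irradiance), the Ek
#' wavelength ratios 625/440, 540/440 and 540/625 (both unit systems), and
#' the paired environmental descriptors (R/B as E625/440, G/B, G/R,
#' Zeu/Zumixl, TSS, stratification flag).
#'
#' Stations lacking one of the wavelengths of a ratio are omitted from that
#' ratio with a message.
#'
#' @param params data.frame with columns `station`, `wavelength`, `r_ek`,
#'   `ek_ii` (one row per station x wavelength)
#' @param stations data.frame with columns `station`, `e_avg`, `ratio_rb`,
#'   `ratio_gb`, `ratio_gr`, `z_eu`, `z_umixl`, `stratified`, `tss`
#' @param pairs wavelength pairs (numerator/denominator) for the Ek ratios
#' @return data.frame, one row per station, with the index columns
#'   `ek440_eavg_r`, `ek440_eavg_ii`, `ek_ratio_<num>_<den>_r` / `_ii` and
#'   the paired environmental variables
#' @export
spectral_indices <- function(params, stations,
                             pairs = list(c(625, 440), c(540, 440), c(540, 625))) {
  stopifnot(all(c("station", "wavelength", "r_ek", "ek_ii") %in% names(params)))
  out <- stations[, intersect(
    c("station", "e_avg", "ratio_rb", "ratio_gb", "ratio_gr",
      "z_eu", "z_umixl", "stratified", "tss"),
    names(stations)
  ), drop = FALSE]

  get_wl <- function(st, wl, col) {
    v <- params[params$station == st & params$wavelength == wl, col]
    if (length(v) != 1L) NA_real_ else v
  }
  sts <- out$station

  out$ek440_eavg_r <- vapply(seq_along(sts), function(i) {
    get_wl(sts[i], 440, "r_ek") / out$e_avg[i]
  }, numeric(1))
  out$ek440_eavg_ii <- vapply(seq_along(sts), function(i) {
    get_wl(sts[i], 440, "ek_ii") / out$e_avg[i]
  }, numeric(1))

  for (pr in pairs) {
    for (us in c("r", "ii")) {
      col <- if (us == "r") "r_ek" else "ek_ii"
      nm <- sprintf("ek_ratio_%d_%d_%s", pr[1], pr[2], us)
      out[[nm]] <- vapply(sts, function(st) {
        get_wl(st, pr[1], col) / get_wl(st, pr[2], col)
      }, numeric(1))
    }
  }
  if ("ratio_rb" %in% names(out)) out$e_625_440 <- out$ratio_rb
  if (all(c("z_eu", "z_umixl") %in% names(out))) {
    out$zeu_zumixl <- out$z_eu / out$z_umixl
  }
  incomplete <- sts[apply(is.na(out[grep("^ek_", names(out))]), 1, any)]
  if (length(incomplete)) {
    message("stations with missing wavelengths omitted from some Ek ratios: ",
            paste(incomplete, collapse = ", "))
  }
  out
}

#' Linear association between two photoacclimation indices
#'
#' Ordinary least-squares line and Pearson correlation (with two-sided
#' p-value) between two columns of an index table, optionally computed
#' separately for stratified and non-stratified stations.
#'
#' @param indices a [spectral_indices()] table (or any data.frame)
#' @param xvar,yvar column names
#' @param by_stratification split on the `stratified` column
#' @return data.frame with one row per group: `group`, `n`, `slope`,
#'   `intercept`, `r`, `p`
#' @export
index_regression <- function(indices, xvar, yvar, by_stratification = FALSE) {
  groups <- if (by_stratification) {
    split(indices, ifelse(indices$stratified, "stratified", "mixed"))
  } else {
    list(all = indices)
  }
  do.call(rbind, lapply(names(groups), function(g) {
    d <- groups[[g]]
    ok <- stats::complete.cases(d[[xvar]], d[[yvar]])
    x <- d[[xvar]][ok]
    y <- d[[yvar]][ok]
    if (length(x) < 3L) {
      return(data.frame(group = g, n = length(x), slope = NA_real_,
                        intercept = NA_real_, r = NA_real_, p = NA_real_))
    }
    fit <- stats::lm(y ~ x)
    ct <- stats::cor.test(x, y)
    data.frame(group = g, n = length(x),
               slope = unname(stats::coef(fit)[2]),
               intercept = unname(stats::coef(fit)[1]),
               r = unname(ct$estimate), p = ct$p.value)
  }))
}
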