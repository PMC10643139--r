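#' Raw BRET ratio of a well
#'
#' `BU = acceptor emission / donor emission` (620 nm over 450 nm filters).
#'
#' @param acceptor_emission,donor_emission Nonnegative emissions (vectorized);
#'   donor must be positive.
#' @return Raw BRET unit(s).
#' @export
#' @examples
#' bret_raw_ratio(50, 1000)
bret_raw_ratio <- function(acceptor_emission, donor_emission) {
  if (any(acceptor_emission < 0)) abort("acceptor emission must be nonnegative.")
  if (any(donor_emission <= 0)) abort("donor emission must be positive.")
  acceptor_emission / donor_emission
}

#' Ligand-control-subtracted milliBRET statistic
#'
#' Per-well `mBU = BU * 1000`; the condition's final value is the mean of the
#' `+ligand` wells minus the mean of the `-ligand` (no-acceptor control)
#' wells. Two technical replicates per arm is the usual design; any number
#' `>= 1` is accepted.
#'
#' @param wells Tibble with columns `ligand` (`"plus"`/`"minus"`), `donor`,
#'   `acceptor`, and optionally `condition` (one condition per call).
#' @return An object of class `ssx_bret` with fields `condition`,
#'   `mean_plus_mbu`, `mean_minus_mbu`, `mbu`, `n_plus`, `n_minus`.
#' @export
#' @examples
#' w <- tibble::tibble(ligand = c("plus", "plus", "minus", "minus"),
#'                     donor = 1000, acceptor = c(50, 50, 20, 20))
#' bret_mbu(w)$mbu
bret_mbu <- function(wells) {
  if (!all(wells$ligand %in% c("plus", "minus"))) {
    abort("`ligand` must be 'plus' or 'minus'.")
  }
  cond <- if ("condition" %in% names(wells)) unique(wells$condition) else "condition"
  if (length(cond) != 1L) abort("bret_mbu() scores one condition at a time.")
  mbu <- 1000 * bret_raw_ratio(wells$acceptor, wells$donor)
  plus <- mbu[wells$ligand == "plus"]
  minus <- mbu[wells$ligand == "minus"]
  if (length(plus) == 0L || length(minus) == 0L) {
    abort("need at least one +ligand and one -ligand well.")
  }
  structure(
    list(condition = cond, mean_plus_mbu = mean(plus),
         mean_minus_mbu = mean(minus), mbu = mean(plus) - mean(minus),
         n_plus = length(plus), n_minus = length(minus)),
    class = "ssx_bret"
  )
}

#' @export
print.ssx_bret <- function(x, ...) {
  cat(sprintf("<ssx_bret> %s: %.4g mBU (+ligand %.4g, -ligand %.4g)\n",
              x$condition, x$mbu, x$mean_plus_mbu, x$mean_minus_mbu))
  invisible(x)
}

#' @method glance ssx_bret
#' @export
glance.ssx_bret <- function(x, ...) {
  tibble::tibble(condition = x$condition, mbu = x$mbu,
                 mean_plus_mbu = x$mean_plus_mbu,
                 mean_minus_mbu = x$mean_minus_mbu,
                 n_plus = x$n_plus, n_minus = x$n_minus)
}

#' Salt-fraction percentages of total protein
#'
#' Band intensities (maximum intensity per band) are expressed as percentages
#' of their sum, the proxy for total protein across the salt-extraction
#' fractions.
#'
#' @param intensities Nonnegative per-fraction band intensities.
#' @param fractions Fraction labels, same length (default: 80/150/300/500 mM
#'   and chromatin when five intensities are given, else `fraction_i`).
#' @return A tibble with `fraction`, `intensity`, `percent`; percentages sum
#'   to 100.
#' @export
#' @examples
#' salt_percentages(c(10, 15, 15, 10, 50))
salt_percentages <- function(intensities, fractions = NULL) {
  if (length(intensities) < 1L) abort("need at least one fraction.")
  if (any(intensities < 0)) abort("band intensities must be nonnegative.")
  total <- sum(intensities)
  if (total <= 0) abort("all band intensities are zero; percentages undefined.")
  if (is.null(fractions)) {
    fractions <- if (length(intensities) == 5L) {
      c("80mM", "150mM", "300mM", "500mM", "chromatin")
    } else {
      paste0("fraction_", seq_along(intensities))
    }
  }
  if (length(fractions) != length(intensities)) {
    abort("`fractions` and `intensities` lengths differ.")
  }
  tibble::tibble(fraction = fractions, intensity = as.numeric(intensities),
                 percent = 100 * intensities / total)
}
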