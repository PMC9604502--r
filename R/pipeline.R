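#' Batch RBE table for a set of spectra
#'
#' Runs [mkm_predict()] on each spectrum and collects the results into a
#' data frame with a stable column order, suitable for CSV export:
#' `label, LET_keV_um, yD_keV_um, alpha_Gy-1, beta_Gy-2, rbe_S<level>...`.
#'
#' @param spectra A non-empty list of [mkm_spectrum()] objects (list names
#'   override spectrum labels).
#' @param params A `cell_line_params` object.
#' @param s_levels Surviving fractions for the RBE columns, default
#'   0.5, 0.1, 0.01.
#' @param out Optional path; when given the table is also written as CSV.
#' @return A data frame, one row per spectrum, in input order.
#' @export
rbe_table <- function(spectra, params, s_levels = c(0.5, 0.1, 0.01),
                      out = NULL) {
  if (!is.list(spectra) || length(spectra) == 0L ||
      is_mkm_spectrum(spectra))
    stop("'spectra' must be a non-empty list of mkm_spectrum objects")
  labels <- names(spectra)
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    lab <- if (!is.null(labels) && nzchar(labels[i])) labels[i]
      else if (!is.null(s$label)) s$label else sprintf("spectrum_%d", i)
    pred <- tryCatch(mkm_predict(s, params, s_levels),
      error = function(e)
        stop("prediction failed for spectrum '", lab, "': ",
             conditionMessage(e), call. = FALSE))
    row <- data.frame(
      label = lab,
      LET_keV_um = if (is.null(s$let)) NA_real_ else s$let,
      yD_keV_um = pred$yD, check.names = FALSE)
    row[["alpha_Gy-1"]] <- pred$alpha
    row[["beta_Gy-2"]] <- pred$beta
    for (j in seq_along(s_levels))
      row[[paste0("rbe_S", names(pred$rbe)[j])]] <- pred$rbe[[j]]
    row
  })
  tab <- do.call(rbind, rows)
  rownames(tab) <- NULL
  if (!is.null(out))
    utils::write.csv(tab, out, row.names = FALSE, quote = FALSE)
  tab
}

# survival-entry rejection rules, applied in this order
.filter_reasons <- c(
  malformed = "missing mandatory field(s)",
  sobp_beam = "cell exposure within a spread-out Bragg peak",
  low_energy = "ion energy below 1 MeV/n",
  synchronized = "synchronized cell population",
  no_photon_reference = "no LQM set with positive alpha_ref and beta_ref",
  negative_beta = "no LQM set with non-negative ion beta",
  zero_alpha_large_beta = "only available ion LQM set has alpha = 0 with large beta")

#' Filter ion-survival database entries
#'
#' Applies the consistency rules used to clean heterogeneous in-vitro
#' clonogenic survival compilations before model benchmarking.  Each entry
#' may carry up to two LQM term sets (an original-publication fit, columns
#' `alpha1`, `beta1`, `alpha_ref1`, `beta_ref1`, and an independent re-fit,
#' columns `alpha2`, ..., any of which may be `NA`).  Entries are rejected,
#' in order, when they are:
#' spread-out-Bragg-peak exposures; ion energies below 1 MeV/n (partial
#' cell irradiation, large dosimetric uncertainty); synchronized
#' populations; lacking any LQM set with positive photon reference terms;
#' lacking any set with a non-negative ion beta; or when the only available
#' ion set has alpha = 0 with beta above `large_beta` (an artifact of
#' constrained fits).  Rows missing mandatory fields (`ion`, `energy_MeV_n`,
#' `beam_type`) are rejected as `malformed` rather than raising an error.
#'
#' @param entries A data frame with columns `ion`, `energy_MeV_n`,
#'   `LET_keV_um`, `beam_type` (`"monoenergetic"` or `"SOBP"`),
#'   `synchronized` (logical), and the LQM columns above.
#' @param large_beta Threshold (Gy^-2) above which a lone alpha = 0 set is
#'   considered a constrained-fit artifact; default 0 (any positive beta).
#' @return A list with data frames `kept` and `rejected`, the latter with a
#'   `reason` code column (see Details for the codes).
#' @export
filter_survival_entries <- function(entries, large_beta = 0) {
  entries <- as.data.frame(entries)
  if (nrow(entries) == 0L)
    return(list(kept = entries,
                rejected = cbind(entries, reason = character(0))))
  for (col in c("ion", "energy_MeV_n", "LET_keV_um", "beam_type",
                "synchronized", "alpha1", "beta1", "alpha_ref1", "beta_ref1",
                "alpha2", "beta2", "alpha_ref2", "beta_ref2"))
    if (is.null(entries[[col]])) entries[[col]] <- NA
  reason <- rep(NA_character_, nrow(entries))
  for (i in seq_len(nrow(entries))) {
    e <- entries[i, ]
    ref_ok <- c(!is.na(e$alpha_ref1) && !is.na(e$beta_ref1) &&
                  e$alpha_ref1 > 0 && e$beta_ref1 > 0,
                !is.na(e$alpha_ref2) && !is.na(e$beta_ref2) &&
                  e$alpha_ref2 > 0 && e$beta_ref2 > 0)
    ion_sets <- list(c(e$alpha1, e$beta1), c(e$alpha2, e$beta2))
    avail <- vapply(ion_sets, function(s) !anyNA(s), TRUE)
    reason[i] <-
      if (is.na(e$ion) || is.na(e$energy_MeV_n) || is.na(e$beam_type))
        "malformed"
      else if (identical(e$beam_type, "SOBP")) "sobp_beam"
      else if (e$energy_MeV_n < 1) "low_energy"
      else if (isTRUE(as.logical(e$synchronized))) "synchronized"
      else if (!any(ref_ok)) "no_photon_reference"
      else if (!any(vapply(ion_sets,
                           function(s) !is.na(s[2]) && s[2] >= 0, TRUE)))
        "negative_beta"
      else if (sum(avail) == 1L &&
               ion_sets[[which(avail)]][1] == 0 &&
               ion_sets[[which(avail)]][2] > large_beta)
        "zero_alpha_large_beta"
      else NA_character_
  }
  kept <- entries[is.na(reason), , drop = FALSE]
  rejected <- entries[!is.na(reason), , drop = FALSE]
  rejected$reason <- reason[!is.na(reason)]
  rownames(kept) <- rownames(rejected) <- NULL
  list(kept = kept, rejected = rejected)
}

#' Generate the deterministic fixture suite
#'
#' Writes, with no randomness, a self-contained set of inputs for
#' exercising the full pipeline: the 14 bundled cell-line configs (one YAML
#' each), a LET sweep of track-segment spectra (1 to 1000 keV/um), photon
#' reference delta spectra at 2.3 and 4.3 keV/um, and a small survival-entry
#' table containing one violation of each filtering rule plus clean rows.
#'
#' @param out_dir Output directory (created if missing).
#' @return A data frame manifest with columns `path` and `type`
#'   (`cell_config`, `spectrum`, `survival_entries`).
#' @export
generate_fixture_suite <- function(out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create fixture directory: ", out_dir)
  manifest <- list()
  add <- function(path, type)
    manifest[[length(manifest) + 1L]] <<- data.frame(path = path, type = type)

  src <- system.file("extdata", "cell_lines.yaml", package = "micromkm",
                     mustWork = TRUE)
  cfgs <- yaml::read_yaml(src)
  for (key in names(cfgs)) {
    p <- file.path(out_dir, paste0("cell_", key, ".yaml"))
    yaml::write_yaml(cfgs[[key]], p)
    add(p, "cell_config")
  }

  for (let in c(1, 2, 5, 10, 20, 50, 100, 200, 500, 1000)) {
    p <- file.path(out_dir, sprintf("track_segment_LET%04d.csv", let))
    write_spectrum(spectrum_track_segment(let), p)
    add(p, "spectrum")
  }
  for (y in c(2.3, 4.3)) {
    p <- file.path(out_dir, sprintf("photon_delta_y%.1f.csv", y))
    write_spectrum(spectrum_delta(y), p)
    add(p, "spectrum")
  }

  toy <- data.frame(
    ion = c("C", "C", "H", "He", "C", "Fe", "H", "C"),
    energy_MeV_n = c(100, 150, 0.5, 10, 50, 200, 5, 20),
    LET_keV_um = c(50, 60, 80, 10, 70, 150, 8, 100),
    beam_type = c("SOBP", "monoenergetic", "monoenergetic", "monoenergetic",
                  "monoenergetic", "monoenergetic", "monoenergetic", NA),
    synchronized = c(FALSE, TRUE, FALSE, FALSE, FALSE, FALSE, FALSE, FALSE),
    alpha1 = c(0.5, 0.5, 0.5, 0.5, 0.5, 0, 0.5, 0.5),
    beta1 = c(0.05, 0.05, 0.05, 0.05, -0.02, 0.3, 0.01, 0.05),
    alpha_ref1 = c(0.2, 0.2, 0.2, NA, 0.2, 0.2, 0.5, 0.2),
    beta_ref1 = c(0.02, 0.02, 0.02, NA, 0.02, 0.02, 0.05, 0.02),
    alpha2 = c(NA, NA, NA, NA, NA, NA, 0.55, NA),
    beta2 = c(NA, NA, NA, NA, NA, NA, 0.02, NA),
    alpha_ref2 = c(NA, NA, NA, NA, NA, NA, 0.52, NA),
    beta_ref2 = c(NA, NA, NA, NA, NA, NA, 0.048, NA))
  p <- file.path(out_dir, "survival_entries_toy.csv")
  utils::write.csv(toy, p, row.names = FALSE)
  add(p, "survival_entries")

  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  out
}

#' Read a survival-entry CSV
#'
#' Thin reader for the entry table consumed by
#' [filter_survival_entries()].
#'
#' @param path CSV path with the columns documented there.
#' @return A data frame.
#' @export
read_survival_entries <- function(path) {
  if (!file.exists(path)) stop("survival-entry file not found: ", path)
  utils::read.csv(path, stringsAsFactors = FALSE)
}
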