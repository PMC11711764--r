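# Centroided MS/MS spectra and Mascot Generic Format (MGF) I/O.

#' Construct a centroided MS/MS spectrum
#'
#' @param scan_id Scan token, unique within a run.
#' @param sample_id Sample token.
#' @param precursor_mz Precursor m/z (Da).
#' @param precursor_charge Positive integer.
#' @param precursor_intensity Precursor intensity (arbitrary units).
#' @param mz,intensity Parallel numeric peak vectors; stored sorted by m/z.
#' @param first_mass Acquisition low-mass cutoff (Da); peaks below it are
#'   dropped (default 110, the usual setting that keeps the CycIm region
#'   observable).
#' @return A `spectrum` object.
#' @export
spectrum <- function(scan_id, sample_id, precursor_mz, precursor_charge,
                     precursor_intensity, mz, intensity, first_mass = 110) {
  stopifnot(length(mz) == length(intensity), all(intensity > 0),
            precursor_charge >= 1L)
  keep <- mz >= first_mass
  ord <- order(mz[keep])
  structure(
    list(scan_id = scan_id, sample_id = sample_id,
         precursor_mz = precursor_mz,
         precursor_charge = as.integer(precursor_charge),
         precursor_intensity = precursor_intensity,
         first_mass = first_mass,
         mz = mz[keep][ord], intensity = intensity[keep][ord]),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf("<spectrum> %s [%s] prec %.4f (%d+), %d peaks, first mass %g\n",
              x$scan_id, x$sample_id, x$precursor_mz, x$precursor_charge,
              length(x$mz), x$first_mass))
  invisible(x)
}

#' Write spectra to an MGF file
#'
#' BEGIN IONS / END IONS blocks with PEPMASS (m/z and precursor intensity),
#' CHARGE, a TITLE carrying scan and sample ids, and a FIRSTMASS line
#' preserving the acquisition cutoff so the file round-trips through
#' [read_mgf()] losslessly.
#'
#' @param spectra List of [spectrum()] objects.
#' @param path Output path.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c(
      "BEGIN IONS",
      sprintf("TITLE=%s sample=%s", s$scan_id, s$sample_id),
      sprintf("PEPMASS=%.6f %.6f", s$precursor_mz, s$precursor_intensity),
      sprintf("CHARGE=%d+", s$precursor_charge),
      sprintf("FIRSTMASS=%.4f", s$first_mass),
      sprintf("%.6f %.6f", s$mz, s$intensity),
      "END IONS"
    ), con)
  }
  invisible(path)
}

#' Read spectra from an MGF file
#' @param path Path to an MGF file written by [write_mgf()] or any MGF with
#'   TITLE/PEPMASS/CHARGE headers.
#' @return List of [spectrum()] objects.
#' @export
read_mgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  stopifnot(length(begins) == length(ends))
  lapply(seq_along(begins), function(i) {
    block <- lines[(begins[i] + 1L):(ends[i] - 1L)]
    is_hdr <- grepl("^[A-Z]+=", block)
    hdr <- block[is_hdr]
    get <- function(key) {
      v <- hdr[startsWith(hdr, paste0(key, "="))]
      if (!length(v)) return(NA_character_)
      sub(paste0("^", key, "="), "", v[1L])
    }
    title <- get("TITLE")
    scan_id <- sub("\\s.*$", "", title)
    sample_id <- if (grepl("sample=", title)) {
      sub("^.*sample=([^ ]+).*$", "\\1", title)
    } else NA_character_
    pm <- as.numeric(strsplit(get("PEPMASS"), "\\s+")[[1]])
    charge <- as.integer(sub("\\+$", "", get("CHARGE")))
    fm <- get("FIRSTMASS")
    peaks <- do.call(rbind, strsplit(block[!is_hdr], "\\s+"))
    mz <- as.numeric(peaks[, 1L]); inten <- as.numeric(peaks[, 2L])
    spectrum(scan_id, sample_id, pm[1L], charge,
             if (length(pm) > 1L) pm[2L] else NA_real_,
             mz, inten,
             first_mass = if (is.na(fm)) min(mz, 110) else as.numeric(fm))
  })
}
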