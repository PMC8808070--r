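## Plain-text readers and writers. All formats are comment-headered
## ASCII: metadata in leading '# key=value' lines, then a delimited
## table. Units are fixed by convention: potentials mV vs SHE, fields
## mT, frequencies GHz, couplings MHz; column names carry the units.

.parseHeader <- function(lines) {
  hdr <- grep("^\\s*#", lines)
  meta <- list()
  for (i in hdr) {
    m <- regmatches(lines[i],
                    regexec("^\\s*#\\s*([A-Za-z0-9_.]+)\\s*=\\s*(.*)$",
                            lines[i]))[[1]]
    if (length(m) == 3) {
      val <- trimws(m[3])
      num <- suppressWarnings(as.numeric(val))
      meta[[m[2]]] <- if (is.na(num)) val else num
    }
  }
  list(meta = meta, nHeader = if (length(hdr)) max(hdr) else 0L)
}

.truthFromMeta <- function(meta) {
  tk <- grep("^truth_", names(meta), value = TRUE)
  stats::setNames(meta[tk], sub("^truth_", "", tk))
}

.readDelimTable <- function(path, required, nHeader, lines) {
  body <- if (nHeader) lines[-seq_len(nHeader)] else lines
  body <- body[nzchar(trimws(body))]
  if (!length(body)) stop("no data rows in ", path)
  sep <- if (grepl(",", body[1])) "," else ""
  dat <- tryCatch(
    utils::read.table(text = body, header = TRUE, sep = sep,
                      strip.white = TRUE, check.names = TRUE),
    error = function(e) stop("cannot parse table in ", path, ": ",
                             conditionMessage(e)))
  for (col in required)
    if (!col %in% names(dat))
      stop("file ", path, " is missing required column '", col, "'")
  for (col in names(dat)) {
    if (!is.numeric(dat[[col]])) {
      rowBad <- which(is.na(suppressWarnings(as.numeric(dat[[col]]))))
      stop("non-numeric value in column '", col, "' of ", path,
           " at data line ", if (length(rowBad)) rowBad[1] else 1,
           " (file line ",
           (if (length(rowBad)) rowBad[1] else 1) + nHeader + 1, ")")
    }
  }
  dat
}

#' Read / write a titration curve
#'
#' CSV/TSV with required columns \code{potential_mV} and
#' \code{amplitude}, optional \code{amplitude_err}; pH, temperature
#' and label in \code{# key=value} header lines (\code{ph},
#' \code{temperature_K}, \code{label}); generator truth, when present,
#' in \code{# truth_*} lines. The write/read round trip is lossless to
#' numerical precision.
#'
#' @param path file path.
#' @return \code{readTitration} returns a
#'   \linkS4class{TitrationCurve}.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' writeTitration(genTitration(seed = 1), tf)
#' readTitration(tf)
#' @export
readTitration <- function(path) {
  lines <- readLines(path)
  h <- .parseHeader(lines)
  dat <- .readDelimTable(path, c("potential_mV", "amplitude"),
                         h$nHeader, lines)
  meta <- h$meta
  titrationCurve(dat$potential_mV, dat$amplitude,
                 amplitudeErr = if ("amplitude_err" %in% names(dat))
                   dat$amplitude_err else numeric(),
                 pH = if (!is.null(meta$ph)) meta$ph else NA_real_,
                 temperature = if (!is.null(meta$temperature_K))
                   meta$temperature_K else 298.15,
                 label = if (!is.null(meta$label)) meta$label else "",
                 truth = .truthFromMeta(meta))
}

#' @param curve a \linkS4class{TitrationCurve}.
#' @param digits significant digits written (default 12).
#' @rdname readTitration
#' @export
writeTitration <- function(curve, path, digits = 12) {
  stopifnot(is(curve, "TitrationCurve"))
  hdr <- c(
    if (!is.na(curve@pH)) sprintf("# ph=%.*g", digits, curve@pH),
    sprintf("# temperature_K=%.*g", digits, curve@temperature),
    if (nzchar(curve@label)) paste0("# label=", curve@label),
    vapply(names(curve@truth), function(k) {
      v <- curve@truth[[k]]
      sprintf("# truth_%s=%s", k,
              if (is.numeric(v)) sprintf("%.*g", digits, v) else
                as.character(v))
    }, character(1)))
  cols <- c("potential_mV", "amplitude")
  dat <- data.frame(potential_mV = curve@potential,
                    amplitude = curve@amplitude)
  if (length(curve@amplitudeErr)) {
    dat$amplitude_err <- curve@amplitudeErr
    cols <- c(cols, "amplitude_err")
  }
  writeLines(c(hdr, paste(cols, collapse = ","),
               apply(dat, 1, function(r)
                 paste(sprintf("%.*g", digits, r), collapse = ","))),
             path)
  invisible(path)
}

#' Read / write an EPR spectrum
#'
#' Two-column whitespace-delimited ASCII (\code{field_mT intensity})
#' with \code{# frequency_GHz=...} and \code{# harmonic=...} header
#' lines. The field axis must be strictly increasing; duplicated field
#' values are reported with their line number.
#'
#' @param path file path.
#' @return \code{readSpectrum} returns an \linkS4class{EPRSpectrum}.
#' @export
readSpectrum <- function(path) {
  lines <- readLines(path)
  h <- .parseHeader(lines)
  if (is.null(h$meta$frequency_GHz))
    stop("file ", path, " is missing the '# frequency_GHz=' header")
  body <- if (h$nHeader) lines[-seq_len(h$nHeader)] else lines
  keep <- which(nzchar(trimws(body)))
  body <- body[keep]
  parts <- strsplit(trimws(body), "[,[:space:]]+")
  if (any(lengths(parts) < 2))
    stop("spectrum line ", keep[which(lengths(parts) < 2)[1]] + h$nHeader,
         " of ", path, " does not have two columns")
  field <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1)))
  inten <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2)))
  if (anyNA(field) || anyNA(inten))
    stop("non-numeric value at line ",
         keep[which(is.na(field) | is.na(inten))[1]] + h$nHeader,
         " of ", path)
  dup <- which(duplicated(field))
  if (length(dup))
    stop("duplicated field value at line ", keep[dup[1]] + h$nHeader,
         " of ", path)
  if (is.unsorted(field, strictly = TRUE))
    stop("field axis in ", path, " is not strictly increasing")
  eprSpectrum(field, inten, h$meta$frequency_GHz,
              harmonic = if (!is.null(h$meta$harmonic))
                h$meta$harmonic else 1L,
              label = if (!is.null(h$meta$label)) h$meta$label else "",
              truth = .truthFromMeta(h$meta))
}

#' @param spectrum an \linkS4class{EPRSpectrum}.
#' @param digits significant digits written (default 12).
#' @rdname readSpectrum
#' @export
writeSpectrum <- function(spectrum, path, digits = 12) {
  stopifnot(is(spectrum, "EPRSpectrum"))
  hdr <- c(sprintf("# frequency_GHz=%.*g", digits,
                   spectrum@frequencyGHz),
           sprintf("# harmonic=%d", spectrum@harmonic),
           if (nzchar(spectrum@label))
             paste0("# label=", spectrum@label),
           vapply(names(spectrum@truth), function(k)
             sprintf("# truth_%s=%.*g", k, digits,
                     as.numeric(spectrum@truth[[k]])), character(1)))
  writeLines(c(hdr, sprintf("%.*g %.*g", digits, spectrum@field,
                            digits, spectrum@intensity)), path)
  invisible(path)
}

#' Read / write a kinetics table
#'
#' CSV with required columns \code{substrate_mM} and \code{rate_U},
#' optional \code{rate_err}; enzyme molar mass and pH in
#' \code{# enzyme_mw_kDa=...} and \code{# ph=...} header lines.
#'
#' @param path file path.
#' @return \code{readKinetics} returns a \linkS4class{KineticsTable}.
#' @export
readKinetics <- function(path) {
  lines <- readLines(path)
  h <- .parseHeader(lines)
  if (is.null(h$meta$enzyme_mw_kDa))
    stop("file ", path, " is missing the '# enzyme_mw_kDa=' header")
  dat <- .readDelimTable(path, c("substrate_mM", "rate_U"),
                         h$nHeader, lines)
  kineticsTable(dat$substrate_mM, dat$rate_U,
                rateErr = if ("rate_err" %in% names(dat))
                  dat$rate_err else numeric(),
                enzymeMW = h$meta$enzyme_mw_kDa,
                pH = if (!is.null(h$meta$ph)) h$meta$ph else NA_real_,
                label = if (!is.null(h$meta$label)) h$meta$label else "",
                truth = .truthFromMeta(h$meta))
}

#' @param table a \linkS4class{KineticsTable}.
#' @param digits significant digits written (default 12).
#' @rdname readKinetics
#' @export
writeKinetics <- function(table, path, digits = 12) {
  stopifnot(is(table, "KineticsTable"))
  hdr <- c(sprintf("# enzyme_mw_kDa=%.*g", digits, table@enzymeMW),
           if (!is.na(table@pH)) sprintf("# ph=%.*g", digits, table@pH),
           if (nzchar(table@label)) paste0("# label=", table@label),
           vapply(names(table@truth), function(k) {
             v <- table@truth[[k]]
             sprintf("# truth_%s=%s", k,
                     if (is.numeric(v)) sprintf("%.*g", digits, v) else
                       as.character(v))
           }, character(1)))
  cols <- c("substrate_mM", "rate_U")
  dat <- data.frame(substrate_mM = table@substrate,
                    rate_U = table@rate)
  if (length(table@rateErr)) {
    dat$rate_err <- table@rateErr
    cols <- c(cols, "rate_err")
  }
  writeLines(c(hdr, paste(cols, collapse = ","),
               apply(dat, 1, function(r)
                 paste(sprintf("%.*g", digits, r), collapse = ","))),
             path)
  invisible(path)
}

#' Read spin systems from a key/value config file
#'
#' One system per block, introduced by \code{[system <label>]}.
#' Recognized keys: \code{g} (3 values), \code{linewidth_mode}
#' (\code{H_strain} or \code{g_strain}), \code{linewidth} (1 or 3
#' FWHM values), \code{weight}, and repeatable \code{hyperfine} lines
#' of the form \code{A1 A2 A3 spin=<I> n=<count>} with A in MHz.
#'
#' @param path config file path.
#' @return Named list of \linkS4class{SpinSystem} objects.
#' @examples
#' cfg <- system.file("extdata", "spin_systems.cfg", package = "EPRedox")
#' names(readSpinSystems(cfg))
#' @export
readSpinSystems <- function(path) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  starts <- grep("^\\s*\\[system\\b", lines)
  if (!length(starts)) stop("no [system ...] blocks in ", path)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- list()
  for (b in seq_along(starts)) {
    label <- trimws(sub("^\\s*\\[system\\s*(.*)\\]\\s*$", "\\1",
                        lines[starts[b]]))
    block <- lines[(starts[b] + 1L):ends[b]]
    kv <- regmatches(block,
                     regexec("^\\s*([A-Za-z_]+)\\s*=\\s*(.*)$", block))
    g <- NULL; mode <- "H_strain"; lw <- 0.5; weight <- 1
    hfs <- list()
    for (i in seq_along(kv)) {
      m <- kv[[i]]
      if (length(m) != 3) next
      key <- m[2]; val <- trimws(m[3])
      if (key == "g") {
        g <- as.numeric(strsplit(val, "\\s+")[[1]])
      } else if (key == "linewidth_mode") {
        mode <- val
      } else if (key == "linewidth") {
        lw <- as.numeric(strsplit(val, "\\s+")[[1]])
      } else if (key == "weight") {
        weight <- as.numeric(val)
      } else if (key == "hyperfine") {
        toks <- strsplit(val, "\\s+")[[1]]
        spin <- 0.5; n <- 1L
        isA <- !grepl("=", toks)
        A <- as.numeric(toks[isA])
        for (t in toks[!isA]) {
          p <- strsplit(t, "=")[[1]]
          if (p[1] == "spin") spin <- as.numeric(p[2])
          if (p[1] == "n") n <- as.integer(p[2])
        }
        hfs[[length(hfs) + 1L]] <- hyperfine(A, spin, n)
      } else {
        stop("unknown key '", key, "' in system block '", label,
             "' of ", path, " (line ", starts[b] + i, ")")
      }
    }
    if (is.null(g))
      stop("system block '", label, "' in ", path, " has no g values")
    out[[label]] <- spinSystem(g, hfs, lwMode = mode, lwWidths = lw,
                               weight = weight, label = label)
  }
  out
}
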