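# The six-axis function-to-form profile: Size, RC.Score, Accessibility,
# Instability, Hydrophobicity, Isoelectric, each normalized onto [0, 1] for
# radar plotting.

.F2F_AXES <- c("Size", "RC.Score", "Accessibility", "Instability",
               "Hydrophobicity", "Isoelectric")

#' Normalize a raw axis value onto \[0, 1\]
#'
#' Linear map `(raw - scale_min) / (scale_max - scale_min)`, clamped.
#'
#' @param raw raw value in native units.
#' @param scale_min,scale_max axis bounds; `scale_max` must exceed
#'   `scale_min`.
#' @return normalized value in \[0, 1\].
#' @export
normalize_axis <- function(raw, scale_min, scale_max) {
  if (scale_max <= scale_min) {
    stop("scale_max must exceed scale_min", call. = FALSE)
  }
  pmin(pmax((raw - scale_min) / (scale_max - scale_min), 0), 1)
}

#' Build the six-parameter profile of a structure
#'
#' Runs the accessibility, Ramachandran and sequence-parameter computations
#' and normalizes each onto its declared scale: Size in kDa against a
#' configurable cap (default 100 kDa), RC.Score / Accessibility /
#' Instability on 0-100 (raw instability above 100 is clamped),
#' Hydrophobicity on -4.5..+4.5 and Isoelectric on pH 0-14.
#'
#' @param s a `prostat_structure`.
#' @param chain chain selection; `NULL` uses all chains.
#' @param size_max Size-axis cap in kDa.
#' @param asa_points Shrake-Rupley test points per atom.
#' @param pka_set pKa set for the isoelectric point.
#' @return an object of class `f2f_profile`: list with `id` and `axes`, a
#'   6-row data.frame (name, raw, scale_min, scale_max, normalized) in fixed
#'   axis order.
#' @export
build_profile <- function(s, chain = NULL, size_max = 100, asa_points = 960,
                          pka_set = "emboss") {
  sel <- if (is.null(chain)) get_chain(s) else get_chain(s, chain)
  axis_try <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("axis '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  seq1 <- axis_try("Size", extract_sequence(sel))
  if (!nzchar(seq1)) stop("axis 'Size' failed: no extractable sequence",
                          call. = FALSE)
  sp <- axis_try("Size", compute_parameters(seq1, pka_set))
  rc <- axis_try("RC.Score", rc_score(sel))
  acc <- axis_try("Accessibility",
                  suppressWarnings(relative_accessibility(sel,
                                                          n_points = asa_points)))
  raw <- c(sp$molecular_weight, rc, acc$rsa,
           if (is.na(sp$instability_index)) 0 else sp$instability_index,
           sp$gravy, sp$isoelectric_point)
  lo <- c(0, 0, 0, 0, -4.5, 0)
  hi <- c(size_max, 100, 100, 100, 4.5, 14)
  axes <- data.frame(name = .F2F_AXES, raw = raw, scale_min = lo,
                     scale_max = hi,
                     normalized = mapply(normalize_axis, raw, lo, hi),
                     stringsAsFactors = FALSE)
  structure(list(id = s$id, axes = axes), class = "f2f_profile")
}

#' Export a profile as radar-plot data
#'
#' @param p an `f2f_profile`.
#' @param format `"json"`, `"csv"` (one row per axis) or `"svg"` (a polygon
#'   with vertex k at angle 2*pi*k/6 and radius = normalized value).
#' @param path optional output file; when `NULL` the text is returned.
#' @return the exported text (invisibly when written to `path`).
#' @export
export_radar <- function(p, format = c("json", "csv", "svg"), path = NULL) {
  format <- match.arg(format)
  stopifnot(inherits(p, "f2f_profile"))
  txt <- switch(format,
    json = jsonlite::toJSON(list(id = p$id, axes = p$axes),
                            dataframe = "rows", auto_unbox = TRUE,
                            digits = NA, pretty = TRUE),
    csv = {
      con <- textConnection("out", "w", local = TRUE)
      utils::write.csv(cbind(id = p$id, p$axes), con, row.names = FALSE)
      close(con)
      paste(c(out, ""), collapse = "\n")
    },
    svg = {
      k <- seq_len(6) - 1
      ang <- 2 * pi * k / 6 - pi / 2
      r <- p$axes$normalized
      xs <- 50 + 45 * r * cos(ang); ys <- 50 + 45 * r * sin(ang)
      pts <- paste(sprintf("%.3f,%.3f", xs, ys), collapse = " ")
      paste0('<svg xmlns="http://www.w3.org/2000/svg" viewBox="0 0 100 100">',
             '<polygon points="', pts,
             '" fill="steelblue" fill-opacity="0.4" stroke="steelblue"/></svg>\n')
    })
  if (!is.null(path)) {
    writeLines(as.character(txt), path, sep = if (format == "json") "\n" else "")
    return(invisible(as.character(txt)))
  }
  as.character(txt)
}

#' Reload an exported JSON profile
#'
#' @param text_or_path JSON text or a file path.
#' @return an `f2f_profile` equal to the exported one.
#' @export
read_radar_json <- function(text_or_path) {
  x <- jsonlite::fromJSON(text_or_path)
  axes <- as.data.frame(x$axes, stringsAsFactors = FALSE)
  axes <- axes[match(.F2F_AXES, axes$name), ]
  rownames(axes) <- NULL
  structure(list(id = x$id, axes = axes), class = "f2f_profile")
}

#' @export
print.f2f_profile <- function(x, ...) {
  cat(sprintf("<f2f profile '%s'>\n", x$id))
  for (i in seq_len(nrow(x$axes))) {
    cat(sprintf("  %-14s raw %10.3f  ->  %.3f\n", x$axes$name[i],
                x$axes$raw[i], x$axes$normalized[i]))
  }
  invisible(x)
}
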