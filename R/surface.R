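#' Dose grid for AKT x MEK inhibitor combination matrices
#'
#' The default grid is the 5 x 6 combination matrix used throughout: a 3-fold
#' dilution series down from 1 uM AKT inhibitor (MK-2206-like axis, 4 nonzero
#' doses) and from 10 uM MEK inhibitor (GSK-1120212-like axis, 5 nonzero
#' doses), each axis including the untreated 0 control, for 30 grid points.
#'
#' @param akt_doses increasing AKT-inhibitor concentrations (uM), first 0.
#' @param mek_doses increasing MEK-inhibitor concentrations (uM), first 0.
#' @return an object of class `dose_grid`.
#' @export
dose_grid <- function(akt_doses = c(0, 1 / 27, 1 / 9, 1 / 3, 1),
                      mek_doses = c(0, 10 / 81, 10 / 27, 10 / 9, 10 / 3, 10)) {
  for (ax in list(akt = akt_doses, mek = mek_doses)) {
    if (any(ax < 0)) stop("dose_grid: doses must be >= 0", call. = FALSE)
    if (is.unsorted(ax, strictly = TRUE)) {
      stop("dose_grid: each axis must be strictly increasing", call. = FALSE)
    }
  }
  if (akt_doses[1] != 0 || mek_doses[1] != 0) {
    stop("dose_grid: each axis must start at the 0 control", call. = FALSE)
  }
  structure(list(akt_doses = akt_doses, mek_doses = mek_doses),
            class = "dose_grid")
}

#' One cell line x heregulin condition's measured response surface
#'
#' @param cell_id cell line identifier.
#' @param hrg logical; `TRUE` for the heregulin-stimulated condition.
#' @param pd matrix of population doublings over 96 h, dimensions matching
#'   `grid` (rows = AKT doses, columns = MEK doses); all entries finite.
#' @param grid a [dose_grid()].
#' @return an object of class `response_surface`.
#' @export
response_surface <- function(cell_id, hrg, pd, grid = dose_grid()) {
  pd <- as.matrix(pd)
  if (!all(dim(pd) == c(length(grid$akt_doses), length(grid$mek_doses)))) {
    stop("response_surface: pd dimensions do not match grid", call. = FALSE)
  }
  if (!all(is.finite(pd))) {
    stop("response_surface: pd must be finite", call. = FALSE)
  }
  structure(list(cell_id = as.character(cell_id), hrg = isTRUE(hrg),
                 grid = grid, pd = pd),
            class = "response_surface")
}

#' @export
print.response_surface <- function(x, ...) {
  cat(sprintf("<response_surface> %s %s: %d x %d grid, PD range [%.2f, %.2f]\n",
              x$cell_id, if (x$hrg) "+HRG" else "-HRG",
              nrow(x$pd), ncol(x$pd), min(x$pd), max(x$pd)))
  invisible(x)
}

#' Read and write response surfaces as long-format CSV
#'
#' Schema: columns `cell_id, hrg (0/1), akt_um, mek_um, pd`, one row per
#' grid point. Values round-trip at the precision stored (15 significant
#' digits). Validation failures report the offending line number.
#'
#' @param surfaces list of [response_surface()] objects.
#' @param file path to a CSV file.
#' @return `read_surfaces` returns a named list of `response_surface`
#'   objects (names `cell_id:hrg`); `write_surfaces` returns `file`
#'   invisibly.
#' @export
write_surfaces <- function(surfaces, file) {
  rows <- lapply(surfaces, function(s) {
    data.frame(cell_id = s$cell_id, hrg = as.integer(s$hrg),
               akt_um = rep(s$grid$akt_doses, times = ncol(s$pd)),
               mek_um = rep(s$grid$mek_doses, each = nrow(s$pd)),
               pd = as.vector(s$pd))
  })
  df <- do.call(rbind, rows)
  utils::write.csv(format(df, digits = 15, scientific = FALSE, trim = TRUE),
                   file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_surfaces
#' @export
read_surfaces <- function(file) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  need <- c("cell_id", "hrg", "akt_um", "mek_um", "pd")
  if (!all(need %in% names(df))) {
    stop("read_surfaces: malformed header; need columns ",
         paste(need, collapse = ", "), call. = FALSE)
  }
  num <- c("akt_um", "mek_um", "pd")
  for (col in num) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad)) {
      stop(sprintf("read_surfaces: non-numeric '%s' at line %d",
                   col, bad[1] + 1L), call. = FALSE)
    }
    df[[col]] <- v
  }
  neg <- which(df$akt_um < 0 | df$mek_um < 0)
  if (length(neg)) {
    stop(sprintf("read_surfaces: negative dose at line %d", neg[1] + 1L),
         call. = FALSE)
  }
  key <- paste(df$cell_id, df$hrg, sep = ":")
  out <- lapply(split(df, factor(key, levels = unique(key))), function(d) {
    akt <- sort(unique(d$akt_um))
    mek <- sort(unique(d$mek_um))
    if (nrow(d) != length(akt) * length(mek)) {
      stop("read_surfaces: incomplete or duplicated grid for ",
           d$cell_id[1], call. = FALSE)
    }
    pd <- matrix(NA_real_, length(akt), length(mek))
    pd[cbind(match(d$akt_um, akt), match(d$mek_um, mek))] <- d$pd
    response_surface(d$cell_id[1], d$hrg[1] == 1, pd,
                     dose_grid(akt, mek))
  })
  out
}

#' @export
surface_key <- function(s) paste(s$cell_id, as.integer(s$hrg), sep = ":")
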