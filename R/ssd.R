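## Seven-segment-display (SSD) serial holography.
##
## Segment numbering (chosen so that the fixed meta-segment group map yields
## pseudo-2D-separable targets: horizontal bars are single y-bands, and the
## two verticals within a group share the same y-band):
##   1 = top bar        2 = upper-right    3 = upper-left
##   4 = bottom bar     5 = lower-right    6 = lower-left
##   7 = middle bar
## Meta-segment group map: No.1 = {1}, No.2 = {2, 3}, No.3 = {4},
## No.4 = {5, 6}, No.5 = {7}.

ssd_code_table <- function() {
  list(
    "0" = c(1, 2, 3, 4, 5, 6), "1" = c(2, 5), "2" = c(1, 2, 7, 6, 4),
    "3" = c(1, 2, 7, 5, 4), "4" = c(3, 2, 7, 5), "5" = c(1, 3, 7, 5, 4),
    "6" = c(1, 3, 7, 6, 5, 4), "7" = c(1, 2, 5), "8" = 1:7,
    "9" = c(1, 2, 3, 7, 5, 4),
    "A" = c(1, 2, 3, 7, 5, 6), "B" = c(3, 6, 7, 5, 4), "C" = c(1, 3, 6, 4),
    "D" = c(2, 5, 6, 7, 4), "E" = c(1, 3, 7, 6, 4), "F" = c(1, 3, 7, 6),
    "G" = c(1, 3, 6, 4, 5), "H" = c(3, 2, 7, 6, 5), "I" = c(2, 5),
    "J" = c(2, 5, 4), "L" = c(3, 6, 4), "N" = c(6, 7, 5),
    "O" = c(1, 2, 3, 4, 5, 6), "P" = c(1, 2, 3, 7, 6), "Q" = c(1, 2, 3, 7, 5),
    "R" = c(6, 7), "S" = c(1, 3, 7, 5, 4), "T" = c(3, 6, 7, 4),
    "U" = c(2, 3, 4, 5, 6), "Y" = c(2, 3, 7, 5, 4),
    " " = integer(0)
  )
}

ssd_group_map <- function() list(`1` = 1L, `2` = c(2L, 3L), `3` = 4L,
                                 `4` = c(5L, 6L), `5` = 7L)

#' Encode text on the seven-segment alphanumeric code
#'
#' @param text character string; digits 0-9, the representable letters (case
#'   insensitive) and space.
#' @return list (one element per character) of active segment id vectors.
#' @export
ssd_encode <- function(text) {
  if (nchar(text) == 0) return(list())
  chars <- strsplit(toupper(text), "")[[1]]
  tab <- ssd_code_table()
  bad <- setdiff(unique(chars), names(tab))
  if (length(bad))
    stop(sprintf("unsupported character(s) for the seven-segment code: %s",
                 paste(bad, collapse = ", ")))
  stats::setNames(lapply(chars, function(ch) tab[[ch]]), chars)
}

#' Seven-segment display layout
#'
#' Geometry of a character cell in target-plane micrometres: segment length,
#' line width and inter-display pitch. Each segment is an axis-aligned
#' rectangle; verticals span half the character height.
#'
#' @param seg_len_um length of a segment in um.
#' @param line_w_um line (stroke) width in um.
#' @param char_pitch_um center-to-center display spacing in um.
#' @return object of class `ssd_layout`.
#' @export
ssd_layout <- function(seg_len_um = 8, line_w_um = 2, char_pitch_um = 14) {
  if (seg_len_um <= 0 || line_w_um <= 0 || char_pitch_um <= seg_len_um)
    stop("invalid layout: lengths must be positive and pitch exceed segment length")
  structure(list(seg_len_um = seg_len_um, line_w_um = line_w_um,
                 char_pitch_um = char_pitch_um),
            class = "ssd_layout")
}

## per-cell segment rectangles (xmin, xmax, ymin, ymax) in um, cell-local
## coordinates with origin at the cell's lower-left corner. Character cell is
## seg_len wide and 2 * seg_len tall.
ssd_segment_rects <- function(layout) {
  L <- layout$seg_len_um; w <- layout$line_w_um; H <- 2 * L
  list(
    `1` = c(0, L, H - w, H),            # top
    `2` = c(L - w, L, H / 2, H),        # upper-right
    `3` = c(0, w, H / 2, H),            # upper-left
    `4` = c(0, L, 0, w),                # bottom
    `5` = c(L - w, L, 0, H / 2),        # lower-right
    `6` = c(0, w, 0, H / 2),            # lower-left
    `7` = c(0, L, H / 2 - w / 2, H / 2 + w / 2)  # middle
  )
}

## rasterize a set of rectangles (um) onto the target-plane grid
rasterize_rects <- function(rects, optics) {
  n <- optics$n_grid
  du <- optics$pitch_target_um
  pat <- matrix(0, n, n)
  c0 <- n %/% 2 + 1
  for (r in rects) {
    ix <- (c0 + round(r[1] / du)):(c0 + round(r[2] / du))
    iy <- (c0 + round(r[3] / du)):(c0 + round(r[4] / du))
    if (any(c(ix, iy) < 1) || any(c(ix, iy) > n))
      stop("SSD text exceeds the field of view")
    pat[ix, iy] <- 1
  }
  pat
}

#' Build the pseudo-2D meta-segment targets for a text
#'
#' Encodes the text, groups the active segments of all characters into the
#' five fixed meta segments (top bars; upper verticals; bottom bars; lower
#' verticals; middle bars), rasterizes each group as a 2D target centered in
#' the field of view, and merges meta segments whose union still passes the
#' rank-1 separability test (recognizing shared axis extents, e.g.
#' y-translated copies of the same x support). Every stored pattern is
#' verified ps2D-separable.
#'
#' @param text supported text (see [ssd_encode()]).
#' @param layout an [ssd_layout()].
#' @param optics an [optical_config()].
#' @param merge logical; merge separability-compatible groups (default TRUE).
#' @return object of class `meta_segment_set`: `text`, `patterns` (list of
#'   2D 0/1 matrices), `groups` (list of meta-group id vectors per pattern),
#'   and `full_pattern`.
#' @export
build_meta_segments <- function(text, layout = ssd_layout(),
                                optics = optical_config(), merge = TRUE) {
  act <- ssd_encode(text)
  nchr <- length(act)
  rects <- ssd_segment_rects(layout)
  gmap <- ssd_group_map()
  # center the text block in the field of view
  width <- if (nchr) (nchr - 1) * layout$char_pitch_um + layout$seg_len_um else 0
  x0 <- -width / 2
  y0 <- -layout$seg_len_um
  group_rects <- stats::setNames(vector("list", 5), names(gmap))
  for (ci in seq_len(nchr)) {
    segs <- act[[ci]]
    for (gi in names(gmap)) {
      hit <- intersect(gmap[[gi]], segs)
      for (s in hit) {
        r <- rects[[as.character(s)]]
        group_rects[[gi]] <- c(group_rects[[gi]],
          list(r + c(x0 + (ci - 1) * layout$char_pitch_um,
                     x0 + (ci - 1) * layout$char_pitch_um, y0, y0)))
      }
    }
  }
  patterns <- list(); groups <- list()
  for (gi in names(group_rects)) {
    if (length(group_rects[[gi]]) == 0) next
    pat <- rasterize_rects(group_rects[[gi]], optics)
    sep <- is_ps2d_separable(pat, tol = 1e-6)
    if (!sep$separable)
      stop(sprintf("internal consistency error: meta group %s not separable", gi))
    patterns <- c(patterns, list(pat))
    groups <- c(groups, list(as.integer(gi)))
  }
  if (merge && length(patterns) > 1) {
    repeat {
      merged <- FALSE
      for (i in seq_along(patterns)) {
        for (j in seq_along(patterns)) {
          if (j <= i) next
          u <- pmax(patterns[[i]], patterns[[j]])
          if (is_ps2d_separable(u, tol = 1e-6)$separable) {
            patterns[[i]] <- u
            groups[[i]] <- sort(c(groups[[i]], groups[[j]]))
            patterns[[j]] <- NULL
            groups[[j]] <- NULL
            merged <- TRUE
            break
          }
        }
        if (merged) break
      }
      if (!merged) break
    }
  }
  full <- if (length(patterns)) Reduce(pmax, patterns) else
    matrix(0, optics$n_grid, optics$n_grid)
  structure(list(text = text, patterns = patterns, groups = groups,
                 full_pattern = full, layout = layout),
            class = "meta_segment_set")
}

#' @export
print.meta_segment_set <- function(x, ...) {
  cat(sprintf("<meta_segment_set> '%s': %d hologram target(s)\n",
              x$text, length(x$patterns)))
  for (i in seq_along(x$patterns))
    cat(sprintf("  target %d: meta group(s) %s, %d active samples\n",
                i, paste(x$groups[[i]], collapse = "+"), sum(x$patterns[[i]] > 0)))
  invisible(x)
}

#' Retrieve the serial hologram sequence for a meta-segment set
#'
#' Factors each stored (separable) target into its axis profiles, retrieves a
#' 1D hologram per axis and composes them. In `"hybrid"` mode the axis with
#' the wider (denser) profile support uses the complex (FM/AM) engine and the
#' orthogonal axis the phase-only static engine; in `"fm"` mode both axes are
#' phase-only. Optional apodization is applied to FM axes. Per-hologram
#' first-order power efficiency (Gaussian input beam) is recorded.
#'
#' @param ms a [build_meta_segments()] result.
#' @param cfg base [ift_config()] for the FM axes; the complex axis uses the
#'   complex-engine default budget with the same seed.
#' @param optics an [optical_config()].
#' @param mode `"hybrid"` or `"fm"`.
#' @param apod_gain apodization gain applied to FM axes (0 = none).
#' @return list of `ps2d_hologram` objects with attribute-like extra fields
#'   `efficiency` and `group`.
#' @export
build_serial_holograms <- function(ms, cfg = ift_config(),
                                   optics = optical_config(),
                                   mode = c("hybrid", "fm"),
                                   apod_gain = 0) {
  mode <- match.arg(mode)
  beam <- beam_profile("gaussian", diameter_samples = optics$n_grid)
  out <- list()
  for (i in seq_along(ms$patterns)) {
    pat <- ms$patterns[[i]]
    if (all(pat == 0)) next
    sep <- is_ps2d_separable(pat, tol = 1e-6)
    if (!sep$separable) stop("stored meta-segment target is not separable")
    tx <- target_1d(sep$profile_x / max(sep$profile_x), optics = optics)
    ty <- target_1d(sep$profile_y / max(sep$profile_y), optics = optics)
    fm_cfg <- cfg; fm_cfg$regularization <- "static"
    retrieve_fm <- function(tg) {
      h <- gs_static(tg, fm_cfg, optics)
      if (apod_gain > 0) h <- apodize(h, apod_gain)
      h
    }
    if (mode == "hybrid") {
      cx_cfg <- ift_config(iterations = 10, seed = cfg$seed,
                           regularization = "complex", gain_max = cfg$gain_max)
      if (sum(tx$target_domain) >= sum(ty$target_domain)) {
        hx <- gs_complex(tx, cx_cfg, optics)
        hy <- retrieve_fm(ty)
      } else {
        hx <- retrieve_fm(tx)
        hy <- gs_complex(ty, cx_cfg, optics)
      }
    } else {
      hx <- retrieve_fm(tx)
      hy <- retrieve_fm(ty)
    }
    ph <- compose(hx, hy, label = sprintf("%s meta %s", ms$text,
                                          paste(ms$groups[[i]], collapse = "+")))
    rec <- reconstruct_2d(ph, aperture = aperture_spec("circular", optics$n_grid),
                          beam = beam, optics = optics)
    ph$efficiency <- rec$metrics$power_efficiency
    ph$group <- ms$groups[[i]]
    out <- c(out, list(ph))
  }
  out
}

#' Sum a sequence of reconstructions
#'
#' Pointwise intensity sum, normalized to unit maximum; models camera
#' accumulation over a serial projection sequence. Optionally applies the
#' two-photon rendering per frame before summing.
#'
#' @param results list of `recon_result` objects (equal shapes).
#' @param two_photon logical; square each frame's intensity first.
#' @return 2D intensity image, maximum 1.
#' @export
sum_reconstructions <- function(results, two_photon = FALSE) {
  if (!length(results)) stop("empty reconstruction sequence")
  frames <- lapply(results, function(r) {
    i <- if (inherits(r, "recon_result")) r$intensity else r
    if (two_photon) i^2 else i
  })
  dims <- vapply(frames, dim, integer(2))
  if (any(dims != dims[, 1])) stop("shape mismatch between frames")
  total <- Reduce(`+`, frames)
  m <- max(total)
  if (m > 0) total / m else total
}
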