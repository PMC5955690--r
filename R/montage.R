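# Electrode montage: idealized 64-channel extended 10-20 layout on the unit
# sphere, with the left/right homologue map used for hemisphere flipping.

#' Construct the standard 64-channel montage
#'
#' Builds an idealized spherical layout for a 64-channel extension of the
#' international 10-20 system. The head is a unit sphere with the vertex (Cz)
#' at the pole; the outer ring (Fp1/Fp2 ... O1/O2) sits at 72 degrees of
#' inclination and interior rows are placed by great-circle (slerp)
#' interpolation between the outer-ring electrode and the corresponding
#' midline electrode, the conventional construction for template montages
#' when no digitized positions exist. Two earlobe electrodes (A1, A2) are
#' included below the equator as reference channels; they are not part of the
#' 64-electrode analysis set.
#'
#' @param include_refs logical; include earlobe reference electrodes A1/A2.
#' @return An object of class `montage`: a list with `labels` (64 scalp
#'   labels), `pos` (matrix, rows = electrodes incl. refs, unit-norm xyz with
#'   +x right, +y anterior, +z up), `ref_labels`, and `lr_pairs` (named
#'   character vector mapping every electrode to its homologue; midline
#'   electrodes map to themselves).
#' @export
#' @examples
#' m <- standard_montage()
#' m$lr_pairs[["C3"]]   # "C4"
standard_montage <- function(include_refs = TRUE) {
  sph <- function(incl_deg, az_deg) {
    th <- incl_deg * pi / 180
    ph <- az_deg * pi / 180
    c(sin(th) * cos(ph), sin(th) * sin(ph), cos(th))
  }
  slerp <- function(p0, p1, t) {
    om <- acos(max(-1, min(1, sum(p0 * p1))))
    if (om < 1e-12) return(p0)
    (sin((1 - t) * om) * p0 + sin(t * om) * p1) / sin(om)
  }

  pos <- list()
  # outer ring, inclination 72 deg; azimuth 90 = nasion, 0 = right ear
  outer <- c(
    T8 = 0, FT8 = 18, F8 = 36, AF8 = 54, Fp2 = 72, Fpz = 90, Fp1 = 108,
    AF7 = 126, F7 = 144, FT7 = 162, T7 = 180, TP7 = 198, P7 = 216,
    PO7 = 234, O1 = 252, Oz = 270, O2 = 288, PO8 = 306, P8 = 324, TP8 = 342
  )
  for (lab in names(outer)) pos[[lab]] <- sph(72, outer[[lab]])
  # midline
  pos$AFz <- sph(54, 90); pos$Fz <- sph(36, 90); pos$FCz <- sph(18, 90)
  pos$Cz <- sph(0, 90)
  pos$CPz <- sph(18, 270); pos$Pz <- sph(36, 270); pos$POz <- sph(54, 270)
  pos$Iz <- sph(90, 270)
  # interior rows: slerp from lateral anchor to midline anchor
  rows <- list(
    list(anchor = c("AF7", "AFz"), labs = "AF3", t = 0.5),
    list(anchor = c("AF8", "AFz"), labs = "AF4", t = 0.5),
    list(anchor = c("F7", "Fz"),  labs = c("F5", "F3", "F1"),  t = c(.25, .5, .75)),
    list(anchor = c("F8", "Fz"),  labs = c("F6", "F4", "F2"),  t = c(.25, .5, .75)),
    list(anchor = c("FT7", "FCz"), labs = c("FC5", "FC3", "FC1"), t = c(.25, .5, .75)),
    list(anchor = c("FT8", "FCz"), labs = c("FC6", "FC4", "FC2"), t = c(.25, .5, .75)),
    list(anchor = c("T7", "Cz"),  labs = c("C5", "C3", "C1"),  t = c(.25, .5, .75)),
    list(anchor = c("T8", "Cz"),  labs = c("C6", "C4", "C2"),  t = c(.25, .5, .75)),
    list(anchor = c("TP7", "CPz"), labs = c("CP5", "CP3", "CP1"), t = c(.25, .5, .75)),
    list(anchor = c("TP8", "CPz"), labs = c("CP6", "CP4", "CP2"), t = c(.25, .5, .75)),
    list(anchor = c("P7", "Pz"),  labs = c("P5", "P3", "P1"),  t = c(.25, .5, .75)),
    list(anchor = c("P8", "Pz"),  labs = c("P6", "P4", "P2"),  t = c(.25, .5, .75)),
    list(anchor = c("PO7", "POz"), labs = "PO3", t = 0.5),
    list(anchor = c("PO8", "POz"), labs = "PO4", t = 0.5)
  )
  for (r in rows) {
    for (i in seq_along(r$labs)) {
      pos[[r$labs[i]]] <- slerp(pos[[r$anchor[1]]], pos[[r$anchor[2]]], r$t[i])
    }
  }
  # inferior temporal pair completing the 64-electrode set
  pos$FT9 <- sph(90, 162); pos$FT10 <- sph(90, 18)

  labels <- names(pos)
  stopifnot(length(labels) == 64L)

  ref_labels <- character(0)
  if (include_refs) {
    pos$A1 <- sph(110, 180); pos$A2 <- sph(110, 0)
    ref_labels <- c("A1", "A2")
  }
  P <- do.call(rbind, pos)
  rownames(P) <- names(pos)

  lr_pairs <- vapply(names(pos), function(lab) {
    mnum <- regmatches(lab, regexpr("[0-9]+$", lab))
    if (length(mnum) == 0) return(lab)            # z-row / Iz: self-mapped
    n <- as.integer(mnum)
    stem <- sub("[0-9]+$", "", lab)
    paste0(stem, if (n %% 2 == 1) n + 1L else n - 1L)
  }, character(1))
  stopifnot(all(lr_pairs %in% names(pos)))

  structure(
    list(labels = labels, pos = P, ref_labels = ref_labels,
         lr_pairs = lr_pairs),
    class = "montage"
  )
}

#' Angular (great-circle) distance between electrode positions
#'
#' @param montage a `montage` object.
#' @param from,to electrode labels; `to` defaults to all electrodes.
#' @return matrix of angles in radians, `length(from)` x `length(to)`.
#' @export
angular_distance <- function(montage, from, to = montage$labels) {
  P <- montage$pos
  stopifnot(all(from %in% rownames(P)), all(to %in% rownames(P)))
  d <- P[from, , drop = FALSE] %*% t(P[to, , drop = FALSE])
  acos(pmin(pmax(d, -1), 1))
}

#' Write / read a montage as a JSON asset
#'
#' @param montage a `montage` object.
#' @param path file path.
#' @export
write_montage <- function(montage, path) {
  jsonlite::write_json(
    list(labels = montage$labels,
         ref_labels = montage$ref_labels,
         lr_pairs = as.list(montage$lr_pairs),
         pos = apply(montage$pos, 1, function(p) as.list(p), simplify = FALSE)),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @rdname write_montage
#' @export
read_montage <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  P <- t(vapply(j$pos, function(p) unlist(p), numeric(3)))
  structure(
    list(labels = j$labels, pos = P, ref_labels = j$ref_labels,
         lr_pairs = unlist(j$lr_pairs)),
    class = "montage"
  )
}

#' Load the packaged 64-channel montage asset
#' @return a `montage` object.
#' @export
load_montage <- function() {
  path <- system.file("extdata", "montage64.json", package = "oscmotor")
  if (nzchar(path) && file.exists(path)) read_montage(path) else standard_montage()
}

#' @export
print.montage <- function(x, ...) {
  cat(sprintf("<montage> %d scalp electrodes", length(x$labels)))
  if (length(x$ref_labels)) cat(sprintf(" + refs: %s", paste(x$ref_labels, collapse = ", ")))
  cat("\n")
  invisible(x)
}
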