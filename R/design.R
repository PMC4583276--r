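#' @keywords internal
"_PACKAGE"

# Experiment design: morph arithmetic, calibration-level interpolation,
# test-face enumeration and block construction for the two-family
# face-categorization task.  Families are abstracted to "A"/"B" ("Jones" and
# "Smith" survive only as display aliases); evidence strengths are "w" < "m"
# < "s"; morph levels are percent own-family throughout (never rounded).

STRENGTHS <- c("w", "m", "s")
FAMILIES <- c("A", "B")
LOCATIONS <- c("top", "bottom")
FAMILY_ALIASES <- c(A = "Jones", B = "Smith")

#' Morph two images
#'
#' A morph is a pixelwise linear combination of two same-shape gray-scale
#' images: `w * A + (1 - w) * B`.
#'
#' @param image_a,image_b Numeric matrices of identical dimensions.
#' @param w Weight on `image_a`, in \[0, 1\].
#' @return A numeric matrix of the same shape.
#' @examples
#' morph_arrays(matrix(0, 2, 2), matrix(100, 2, 2), 0.75)
#' @export
morph_arrays <- function(image_a, image_b, w) {
  if (!is.numeric(image_a) || !is.numeric(image_b)) {
    stop("images must be numeric arrays")
  }
  if (!identical(dim(image_a), dim(image_b)) ||
      length(image_a) != length(image_b)) {
    stop("image shapes differ: cannot morph")
  }
  if (!is.numeric(w) || length(w) != 1L || is.na(w) || w < 0 || w > 1) {
    stop("morph weight `w` must be a single number in [0, 1]")
  }
  w * image_a + (1 - w) * image_b
}

#' Derive weak and strong morph levels from a calibrated medium level
#'
#' The weak level lies midway between the medium level and a 50% (fully
#' ambiguous) morph; the strong level lies two-thirds of the way from the
#' medium level to a 100% (target) morph.
#'
#' @param medium Medium morph level, percent own-family in \[50, 100\].
#' @return A named list with numeric elements `weak` and `strong` (percent).
#' @examples
#' derive_levels(82) # weak 66, strong 94
#' @export
derive_levels <- function(medium) {
  if (!is.numeric(medium) || anyNA(medium) || any(medium < 50) ||
      any(medium > 100)) {
    stop("`medium` must lie in [50, 100] percent")
  }
  list(weak = (medium + 50) / 2, strong = medium + (2 / 3) * (100 - medium))
}

#' Calibration levels for every half-face staircase
#'
#' Builds the per-(location x family) table of weak/medium/strong morph
#' levels from the four calibrated medium levels.
#'
#' @param mediums Named numeric vector of medium levels (percent) with names
#'   `top.A`, `top.B`, `bottom.A`, `bottom.B`; a single unnamed value is
#'   recycled to all four staircases.
#' @return A data frame with columns `location`, `family`, `weak`, `medium`,
#'   `strong`, of class `mcia_calibration`.
#' @examples
#' calibration_levels(82)
#' @export
calibration_levels <- function(mediums = 82) {
  keys <- as.vector(outer(LOCATIONS, FAMILIES, paste, sep = "."))
  if (length(mediums) == 1L && is.null(names(mediums))) {
    mediums <- stats::setNames(rep(as.numeric(mediums), 4L), keys)
  }
  if (!all(keys %in% names(mediums))) {
    stop("`mediums` must be named with: ", paste(keys, collapse = ", "))
  }
  m <- as.numeric(mediums[keys])
  ws <- derive_levels(m)
  out <- data.frame(
    location = rep(LOCATIONS, times = 2L),
    family = rep(FAMILIES, each = 2L),
    weak = ws$weak, medium = m, strong = ws$strong,
    stringsAsFactors = FALSE
  )
  class(out) <- c("mcia_calibration", "data.frame")
  out
}

#' Write or read calibration levels as JSON
#'
#' Serialized keyed by location then family, each holding the weak, medium
#' and strong percents.
#'
#' @param levels A calibration table from [calibration_levels()].
#' @param path File path.
#' @return `read_calibration()` returns the calibration table.
#' @export
write_calibration <- function(levels, path) {
  stopifnot(inherits(levels, "mcia_calibration"))
  obj <- lapply(split(levels, levels$location), function(loc) {
    lapply(split(loc, loc$family), function(r) {
      list(weak = r$weak, medium = r$medium, strong = r$strong)
    })
  })
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  mediums <- unlist(lapply(names(obj), function(loc) {
    stats::setNames(
      vapply(obj[[loc]], function(x) x$medium, numeric(1)),
      paste(loc, names(obj[[loc]]), sep = ".")
    )
  }))
  calibration_levels(mediums)
}

lookup_level <- function(levels, location, strength, family) {
  name <- c(w = "weak", m = "medium", s = "strong")[strength]
  idx <- match(
    paste(location, family),
    paste(levels$location, levels$family)
  )
  vapply(seq_along(idx), function(i) levels[[name[i]]][idx[i]], numeric(1))
}

#' Enumerate the 56 test faces
#'
#' Generates the full test-face set: 12 half faces (3 strengths x 2
#' locations x 2 families), 36 whole faces (3 x 3 strength crossings x 2
#' families, each in together and split format), and 8 opposite faces
#' (medium paired with weak from the other family, 2 top strengths x 2 top
#' families, each in both formats).  Opposite faces check that weak evidence
#' for one family is not read as evidence for the other.
#'
#' @param levels Calibration table from [calibration_levels()]; fills the
#'   `*_morph` percent columns.
#' @return A data frame of 56 rows with columns `format` (`half`,
#'   `together`, `split`), `top_family`, `top_strength`, `top_morph`,
#'   `bottom_family`, `bottom_strength`, `bottom_morph` (NA for the absent
#'   half of a half face).
#' @export
enumerate_test_faces <- function(levels = calibration_levels()) {
  stopifnot(inherits(levels, "mcia_calibration"))
  face_row <- function(format, tf, ts, bf, bs) {
    data.frame(
      format = format,
      top_family = if (is.na(tf)) NA_character_ else tf,
      top_strength = if (is.na(ts)) NA_character_ else ts,
      top_morph = if (is.na(ts)) NA_real_ else
        lookup_level(levels, "top", ts, tf),
      bottom_family = if (is.na(bf)) NA_character_ else bf,
      bottom_strength = if (is.na(bs)) NA_character_ else bs,
      bottom_morph = if (is.na(bs)) NA_real_ else
        lookup_level(levels, "bottom", bs, bf),
      stringsAsFactors = FALSE
    )
  }
  rows <- list()
  # 12 half faces
  for (fam in FAMILIES) for (st in STRENGTHS) {
    rows <- c(rows, list(
      face_row("half", fam, st, NA, NA),
      face_row("half", NA, NA, fam, st)
    ))
  }
  # 36 whole faces: same family top and bottom, both formats
  for (fmt in c("together", "split")) for (fam in FAMILIES) {
    for (ts in STRENGTHS) for (bs in STRENGTHS) {
      rows <- c(rows, list(face_row(fmt, fam, ts, fam, bs)))
    }
  }
  # 8 opposite faces: medium vs weak across families, both formats
  for (fmt in c("together", "split")) for (tf in FAMILIES) {
    bf <- setdiff(FAMILIES, tf)
    rows <- c(rows, list(
      face_row(fmt, tf, "m", bf, "w"),
      face_row(fmt, tf, "w", bf, "m")
    ))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Classify a face as half, whole, or opposite
#'
#' @param faces A face data frame (rows from [enumerate_test_faces()]).
#' @return Character vector: `"half"`, `"whole"` (both halves, same
#'   family), or `"opposite"` (halves from different families).
#' @export
face_type <- function(faces) {
  ifelse(is.na(faces$top_family) | is.na(faces$bottom_family), "half",
    ifelse(faces$top_family == faces$bottom_family, "whole", "opposite")
  )
}

#' Correct response family for each face
#'
#' For half and same-family whole faces the correct response is that
#' family; for opposite faces it is the family of the stronger (medium)
#' half.
#'
#' @param faces A face data frame.
#' @return Character vector of family labels.
#' @export
correct_family <- function(faces) {
  type <- face_type(faces)
  strength_rank <- function(s) match(s, STRENGTHS)
  out <- character(nrow(faces))
  half <- type == "half"
  out[half] <- ifelse(is.na(faces$top_family[half]),
    faces$bottom_family[half], faces$top_family[half]
  )
  whole <- type == "whole"
  out[whole] <- faces$top_family[whole]
  opp <- type == "opposite"
  top_stronger <- strength_rank(faces$top_strength[opp]) >
    strength_rank(faces$bottom_strength[opp])
  out[opp] <- ifelse(top_stronger, faces$top_family[opp],
    faces$bottom_family[opp]
  )
  out
}

#' Collapsed condition label
#'
#' Collapses a face to its analysis condition: half faces to `w`/`m`/`s`,
#' same-family wholes to the unordered strength pair (`ww`, `wm`, `ws`,
#' `mm`, `ms`, `ss`), and opposite faces to `wom`.  Family and
#' top-vs-bottom location are dropped; `w/s` and `s/w` share the `ws` cell.
#'
#' @param faces A face data frame.
#' @return Character vector of condition labels.
#' @export
condition_label <- function(faces) {
  type <- face_type(faces)
  out <- character(nrow(faces))
  half <- type == "half"
  out[half] <- ifelse(is.na(faces$top_strength[half]),
    faces$bottom_strength[half], faces$top_strength[half]
  )
  whole <- type == "whole"
  if (any(whole)) {
    i <- match(faces$top_strength[whole], STRENGTHS)
    j <- match(faces$bottom_strength[whole], STRENGTHS)
    lo <- pmin(i, j)
    hi <- pmax(i, j)
    out[whole] <- paste0(STRENGTHS[lo], STRENGTHS[hi])
  }
  out[type == "opposite"] <- "wom"
  out
}

#' Build one 68-trial integration block
#'
#' Each of the 56 test faces appears once; the equal-strength whole faces
#' (`w/w`, `m/m`, `s/s` in both families and both formats, 12 faces) appear
#' twice, giving 68 trials.  Trial order is shuffled and each trial is
#' assigned one of nine screen positions (x and y offsets from
#' \{-100, 0, +100\} pixels) uniformly at random, to randomize starting eye
#' fixation.
#'
#' @param faces The full 56-face enumeration.
#' @param seed Integer seed for the shuffle; identical seeds give identical
#'   blocks.
#' @return The face data frame expanded to 68 rows with `trial_index`,
#'   `screen_x`, `screen_y` columns prepended.
#' @export
build_block <- function(faces, seed) {
  if (nrow(faces) != 56L) {
    stop("`faces` must be the full 56-face enumeration, got ", nrow(faces))
  }
  type <- face_type(faces)
  equal_whole <- type == "whole" &
    faces$top_strength == faces$bottom_strength
  if (sum(equal_whole) != 12L) {
    stop("face list is not a valid enumeration: expected 12 equal-strength ",
         "whole faces, found ", sum(equal_whole))
  }
  idx <- c(seq_len(nrow(faces)), which(equal_whole))
  offsets <- c(-100, 0, 100)
  withr::with_seed(seed, {
    idx <- sample(idx)
    block <- faces[idx, , drop = FALSE]
    block <- cbind(
      trial_index = seq_along(idx),
      screen_x = sample(offsets, length(idx), replace = TRUE),
      screen_y = sample(offsets, length(idx), replace = TRUE),
      block
    )
  })
  rownames(block) <- NULL
  block
}
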