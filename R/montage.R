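# 32-electrode 10-20 montage with the channel bookkeeping the feature
# families need: a 29-channel feature subset, 13 mirrored left-right pairs
# (DASM/RASM) and 11 frontal-posterior pairs (DCAU).

#' The seven landscape stimulus classes
#'
#' @return character vector of class names in class-id order (1..7).
#' @export
landscape_classes <- function() {
  c("forest", "wetland", "grassland", "desert", "water", "farmland", "city")
}

# Schematic 2-D scalp coordinates (head seen from above, x positive to the
# right, y positive to the front, unit head radius).
.electrode_table <- function() {
  e <- rbind(
    c("Fp1", -0.31,  0.95), c("Fp2",  0.31,  0.95),
    c("F7",  -0.81,  0.59), c("F3",  -0.43,  0.56), c("Fz", 0,  0.55),
    c("F4",   0.43,  0.56), c("F8",   0.81,  0.59),
    c("FT9", -0.98,  0.33), c("FT10", 0.98,  0.33),
    c("FC5", -0.67,  0.30), c("FC1", -0.25,  0.28),
    c("FC2",  0.25,  0.28), c("FC6",  0.67,  0.30),
    c("T7",  -1.00,  0.00), c("C3",  -0.50,  0.00), c("Cz", 0,  0.00),
    c("C4",   0.50,  0.00), c("T8",   1.00,  0.00),
    c("TP9", -1.05, -0.33), c("TP10", 1.05, -0.33),
    c("CP5", -0.67, -0.30), c("CP1", -0.25, -0.28),
    c("CP2",  0.25, -0.28), c("CP6",  0.67, -0.30),
    c("P7",  -0.81, -0.59), c("P3",  -0.43, -0.56), c("Pz", 0, -0.55),
    c("P4",   0.43, -0.56), c("P8",   0.81, -0.59),
    c("O1",  -0.31, -0.95), c("Oz",   0.00, -1.00), c("O2", 0.31, -0.95)
  )
  data.frame(label = e[, 1], x = as.numeric(e[, 2]), y = as.numeric(e[, 3]),
             stringsAsFactors = FALSE)
}

#' Default 32-channel montage
#'
#' A standard 32-channel actiCAP-style 10-20 layout. TP9/TP10 are the
#' left/right mastoid references; Oz is additionally excluded from feature
#' extraction, leaving 29 feature channels. Thirteen mirror-symmetric
#' left-right pairs feed the asymmetry features and eleven frontal-posterior
#' pairs feed the caudality feature. The original acquisition montage is not
#' published channel-by-channel; this default reproduces every printed count
#' (29 feature channels, 13 and 11 pairs) and can be replaced via the config.
#'
#' @return An object of class `eeg_montage`: list with `electrodes`
#'   (data.frame label/x/y), `reference_labels`, `feature_channels`,
#'   `lr_pairs` (13 x 2 character matrix, left column first), `fp_pairs`
#'   (11 x 2, frontal column first).
#' @export
default_montage <- function() {
  el <- .electrode_table()
  refs <- c("TP9", "TP10")
  feat <- setdiff(el$label, c(refs, "Oz"))
  lr <- rbind(
    c("Fp1", "Fp2"), c("F3", "F4"), c("F7", "F8"), c("FC1", "FC2"),
    c("FC5", "FC6"), c("C3", "C4"), c("T7", "T8"), c("CP1", "CP2"),
    c("CP5", "CP6"), c("P3", "P4"), c("P7", "P8"), c("O1", "O2"),
    c("FT9", "FT10")
  )
  fp <- rbind(
    c("Fp1", "O1"), c("Fp2", "O2"), c("F3", "P3"), c("F4", "P4"),
    c("F7", "P7"), c("F8", "P8"), c("FC1", "CP1"), c("FC2", "CP2"),
    c("FC5", "CP5"), c("FC6", "CP6"), c("Fz", "Pz")
  )
  colnames(lr) <- c("left", "right")
  colnames(fp) <- c("frontal", "posterior")
  structure(list(electrodes = el, reference_labels = refs,
                 feature_channels = feat, lr_pairs = lr, fp_pairs = fp),
            class = "eeg_montage")
}

#' Validate a montage
#'
#' Checks the structural invariants the feature dimensionalities depend on:
#' 29 feature channels, 13 left-right and 11 frontal-posterior pairs, all
#' pair members inside the feature subset, references outside it, and
#' mirror symmetry of the left-right pairs in the scalp coordinates.
#'
#' @param montage an `eeg_montage`.
#' @return character vector of human-readable violations; empty if valid.
#' @export
validate_montage <- function(montage) {
  v <- character()
  el <- montage$electrodes$label
  if (length(montage$feature_channels) != 29L)
    v <- c(v, sprintf("feature_channels has %d labels, expected 29",
                      length(montage$feature_channels)))
  if (nrow(montage$lr_pairs) != 13L)
    v <- c(v, sprintf("lr_pairs has %d pairs, expected 13",
                      nrow(montage$lr_pairs)))
  if (nrow(montage$fp_pairs) != 11L)
    v <- c(v, sprintf("fp_pairs has %d pairs, expected 11",
                      nrow(montage$fp_pairs)))
  unknown <- setdiff(c(montage$feature_channels, montage$reference_labels,
                       c(montage$lr_pairs), c(montage$fp_pairs)), el)
  if (length(unknown))
    v <- c(v, paste("labels not in electrode table:",
                    paste(unknown, collapse = ", ")))
  bad <- setdiff(c(montage$lr_pairs, montage$fp_pairs),
                 montage$feature_channels)
  if (length(bad))
    v <- c(v, paste("pair members outside feature_channels:",
                    paste(unique(bad), collapse = ", ")))
  inref <- intersect(montage$reference_labels, montage$feature_channels)
  if (length(inref))
    v <- c(v, paste("reference labels inside feature_channels:",
                    paste(inref, collapse = ", ")))
  # mirror symmetry of lr pairs in the coordinates
  co <- montage$electrodes
  rownames(co) <- co$label
  for (i in seq_len(nrow(montage$lr_pairs))) {
    l <- montage$lr_pairs[i, 1]; r <- montage$lr_pairs[i, 2]
    if (l %in% el && r %in% el) {
      if (abs(co[l, "x"] + co[r, "x"]) > 1e-9 ||
          abs(co[l, "y"] - co[r, "y"]) > 1e-9)
        v <- c(v, sprintf("lr_pair (%s, %s) is not mirror symmetric", l, r))
      if (!(co[l, "x"] < 0 && co[r, "x"] > 0))
        v <- c(v, sprintf("lr_pair (%s, %s) is not ordered left-right", l, r))
    }
  }
  for (i in seq_len(nrow(montage$fp_pairs))) {
    f <- montage$fp_pairs[i, 1]; p <- montage$fp_pairs[i, 2]
    if (f %in% el && p %in% el && !(co[f, "y"] > co[p, "y"]))
      v <- c(v, sprintf("fp_pair (%s, %s) is not ordered front-back", f, p))
  }
  v
}

#' Positions of channel labels in a recording's channel order
#'
#' @param labels character vector of electrode labels to locate.
#' @param channel_labels the recording's ordered channel labels (or an
#'   `eeg_montage`, whose electrode order is used).
#' @return integer vector of 1-based positions, parallel to `labels`.
#' @export
channel_index <- function(labels, channel_labels) {
  if (inherits(channel_labels, "eeg_montage"))
    channel_labels <- channel_labels$electrodes$label
  idx <- match(labels, channel_labels)
  if (anyNA(idx))
    stop("unknown channel label(s): ",
         paste(labels[is.na(idx)], collapse = ", "))
  idx
}

#' Build a montage from a config section
#'
#' Accepts the string "default" or a list with `electrodes` (list of
#' `label: [x, y]`), `reference_labels`, `feature_channels`, `lr_pairs`
#' and `fp_pairs` (lists of two-element label lists). The result is
#' validated; violations are an error.
#'
#' @param spec "default" or a montage description list (e.g. from YAML).
#' @return an `eeg_montage`.
#' @export
montage_from_config <- function(spec) {
  if (identical(spec, "default")) return(default_montage())
  if (!is.list(spec)) stop("montage config must be 'default' or a list")
  el <- data.frame(label = names(spec$electrodes),
                   x = vapply(spec$electrodes, function(p) p[[1]], 0),
                   y = vapply(spec$electrodes, function(p) p[[2]], 0),
                   stringsAsFactors = FALSE)
  as_pairs <- function(p, nm) {
    m <- do.call(rbind, lapply(p, unlist))
    colnames(m) <- nm
    m
  }
  montage <- structure(list(
    electrodes = el,
    reference_labels = unlist(spec$reference_labels),
    feature_channels = unlist(spec$feature_channels),
    lr_pairs = as_pairs(spec$lr_pairs, c("left", "right")),
    fp_pairs = as_pairs(spec$fp_pairs, c("frontal", "posterior"))),
    class = "eeg_montage")
  v <- validate_montage(montage)
  if (length(v))
    stop("invalid montage config:\n  ", paste(v, collapse = "\n  "))
  montage
}

#' @export
print.eeg_montage <- function(x, ...) {
  cat(sprintf("<eeg_montage> %d electrodes, refs %s, %d feature channels, %d LR pairs, %d FP pairs\n",
              nrow(x$electrodes), paste(x$reference_labels, collapse = "/"),
              length(x$feature_channels), nrow(x$lr_pairs), nrow(x$fp_pairs)))
  invisible(x)
}
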