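#' The 20 canonical 10-20 electrode labels
#'
#' Ordered roughly front to back, left to right; these 20 sites are the
#' nodes of every connectivity network in the package.
#'
#' @return Character vector of length 20.
#' @export
canonical_channels <- function() {
  c("FP1", "FP2", "F7", "F3", "Fz", "F4", "F8",
    "T7", "C3", "Cz", "C4", "T8",
    "T5", "P3", "Pz", "P4", "T6",
    "O1", "Oz", "O2")
}

#' Construct an electrode montage
#'
#' A montage is an ordered set of channel labels plus a symmetric
#' nearest-neighbour adjacency used by the Hjorth surface Laplacian.
#'
#' @param labels Ordered channel names.
#' @param neighbors Named list mapping each label to a character vector of
#'   adjacent labels. The relation must be symmetric.
#' @return An object of class `montage`.
#' @export
montage <- function(labels, neighbors) {
  stopifnot(is.character(labels), !anyDuplicated(labels))
  if (!all(names(neighbors) %in% labels)) {
    stop("neighbor table refers to labels not in the montage")
  }
  for (lab in names(neighbors)) {
    nb <- neighbors[[lab]]
    if (!all(nb %in% labels)) {
      stop("unknown neighbor label(s) for ", lab, ": ",
           paste(setdiff(nb, labels), collapse = ", "))
    }
    for (other in nb) {
      if (!(lab %in% neighbors[[other]])) {
        stop("neighbor relation not symmetric: ", lab, " -> ", other)
      }
    }
  }
  structure(list(labels = labels, neighbors = neighbors), class = "montage")
}

#' Idealized 10-20 montage for the 20 canonical electrodes
#'
#' Nearest-neighbour adjacency on the standard 10-20 layout (Hjorth
#' Laplacian support). The table is symmetric by construction.
#'
#' @return A `montage` object over [canonical_channels()].
#' @export
montage_1020 <- function() {
  nb <- list(
    FP1 = c("FP2", "F7", "F3"),
    FP2 = c("FP1", "F4", "F8"),
    F7  = c("FP1", "F3", "T7"),
    F3  = c("FP1", "F7", "Fz", "C3"),
    Fz  = c("F3", "F4", "Cz"),
    F4  = c("FP2", "F8", "Fz", "C4"),
    F8  = c("FP2", "F4", "T8"),
    T7  = c("F7", "C3", "T5"),
    C3  = c("F3", "T7", "Cz", "P3"),
    Cz  = c("Fz", "C3", "C4", "Pz"),
    C4  = c("F4", "T8", "Cz", "P4"),
    T8  = c("F8", "C4", "T6"),
    T5  = c("T7", "P3", "O1"),
    P3  = c("C3", "T5", "Pz", "O1"),
    Pz  = c("Cz", "P3", "P4", "Oz"),
    P4  = c("C4", "T6", "Pz", "O2"),
    T6  = c("T8", "P4", "O2"),
    O1  = c("T5", "P3", "Oz"),
    Oz  = c("O1", "O2", "Pz"),
    O2  = c("T6", "P4", "Oz")
  )
  montage(canonical_channels(), nb)
}

#' @export
print.montage <- function(x, ...) {
  cat("<montage> ", length(x$labels), " channels: ",
      paste(x$labels, collapse = " "), "\n", sep = "")
  invisible(x)
}
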