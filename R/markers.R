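#' The canonical 22-marker set
#'
#' Marker labels for the full-body set used throughout the package: four head
#' markers (anterior/posterior x left/right), bilateral markers on the wrist
#' (ulna styloid process), elbow (lateral humeral epicondyle), shoulder
#' (acromion), posterior and anterior iliac spines, knee (lateral femoral
#' epicondyle), ankle (lateral malleolus) and big toe (distal phalange 1),
#' plus a sternum marker and one on the centre of the right thigh.
#'
#' Bilateral labels carry a `_L`/`_R` suffix; `sternum` is unilateral and the
#' thigh marker exists on the right side only.
#'
#' @return Character vector of 22 marker labels, in canonical order.
#' @export
#' @examples
#' exerstep_markers()
exerstep_markers <- function() {
  bilateral <- c("head_front", "head_back", "wrist", "elbow", "shoulder",
                 "ilium_post", "ilium_ant", "knee", "ankle", "toe")
  c(as.vector(t(outer(bilateral, c("_L", "_R"), paste0))), "sternum", "thigh_R")
}

#' Side tag of a marker label
#'
#' @param labels character vector of canonical marker labels.
#' @return Character vector: `"left"`, `"right"` or `"none"` per label.
#' @export
marker_side <- function(labels) {
  out <- rep("none", length(labels))
  out[endsWith(labels, "_L")] <- "left"
  out[endsWith(labels, "_R")] <- "right"
  out
}

#' Default marker alias table
#'
#' Maps common vendor-style export labels onto the canonical names of
#' [exerstep_markers()]. Matching (see [canonicalize_labels()]) is
#' case-insensitive and ignores spaces, dots and dashes, so e.g.
#' `"L_Toe"`, `"l.toe"` and `"LToe"` all resolve to `toe_L`.
#'
#' @return `data.frame` with columns `alias` and `canonical`.
#' @export
default_marker_aliases <- function() {
  pairs <- c(
    "lheadfront" = "head_front_L", "rheadfront" = "head_front_R",
    "lheadback"  = "head_back_L",  "rheadback"  = "head_back_R",
    "lheadant"   = "head_front_L", "rheadant"   = "head_front_R",
    "lheadpost"  = "head_back_L",  "rheadpost"  = "head_back_R",
    "lwrist"     = "wrist_L",      "rwrist"     = "wrist_R",
    "lwra"       = "wrist_L",      "rwra"       = "wrist_R",
    "lelbow"     = "elbow_L",      "relbow"     = "elbow_R",
    "lshoulder"  = "shoulder_L",   "rshoulder"  = "shoulder_R",
    "lacromion"  = "shoulder_L",   "racromion"  = "shoulder_R",
    "lpsis"      = "ilium_post_L", "rpsis"      = "ilium_post_R",
    "lasis"      = "ilium_ant_L",  "rasis"      = "ilium_ant_R",
    "lknee"      = "knee_L",       "rknee"      = "knee_R",
    "lankle"     = "ankle_L",      "rankle"     = "ankle_R",
    "lmalleolus" = "ankle_L",      "rmalleolus" = "ankle_R",
    "ltoe"       = "toe_L",        "rtoe"       = "toe_R",
    "chest"      = "sternum",      "sternum"    = "sternum",
    "rthigh"     = "thigh_R",      "thigh"      = "thigh_R"
  )
  data.frame(alias = names(pairs), canonical = unname(pairs))
}

squash_label <- function(x) gsub("[ ._-]", "", tolower(x))

#' Map raw trajectory labels to the canonical marker set
#'
#' @param labels character vector of labels as found in a file.
#' @param aliases alias table as returned by [default_marker_aliases()];
#'   additional rows may be appended for lab-specific naming.
#' @return Character vector of canonical labels; labels that are already
#'   canonical pass through, unknown labels are returned unchanged.
#' @export
canonicalize_labels <- function(labels, aliases = default_marker_aliases()) {
  canon <- exerstep_markers()
  key <- squash_label(labels)
  out <- labels
  # exact canonical names (squashed) first, then the alias table
  hit <- match(key, squash_label(canon))
  out[!is.na(hit)] <- canon[hit[!is.na(hit)]]
  left <- is.na(hit)
  if (any(left)) {
    ahit <- match(key[left], squash_label(aliases$alias))
    out[left][!is.na(ahit)] <- aliases$canonical[ahit[!is.na(ahit)]]
  }
  out
}
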