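#' Halpe full-body keypoint names
#'
#' The fixed, ordered set of 26 keypoint labels emitted by the Halpe
#' full-body pose model (AlphaPose output dialect). The order matters: flat
#' `keypoints` arrays in pose JSON are interpreted as (x, y, confidence)
#' triplets in exactly this order.
#'
#' @return Character vector of length 26.
#' @export
#' @examples
#' halpe_keypoints()[c(21, 25)] # left big toe, left heel
halpe_keypoints <- function() {
  c(
    "Nose", "LEye", "REye", "LEar", "REar",
    "LShoulder", "RShoulder", "LElbow", "RElbow", "LWrist", "RWrist",
    "LHip", "RHip", "LKnee", "RKnee", "LAnkle", "RAnkle",
    "Head", "Neck", "Hip",
    "LBigToe", "RBigToe", "LSmallToe", "RSmallToe",
    "LHeel", "RHeel"
  )
}

# keypoints the gait pipeline actually consumes
.gait_keypoints <- c("LHeel", "RHeel", "LBigToe", "RBigToe")

.assert_keypoint <- function(name) {
  if (!is.character(name) || length(name) != 1L || !(name %in% halpe_keypoints())) {
    stop("unknown keypoint name: ", paste(name, collapse = ", "),
         " (must be one of the 26 Halpe labels)", call. = FALSE)
  }
  invisible(name)
}
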