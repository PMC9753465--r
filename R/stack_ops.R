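#' Maximum-value projection of a whole z-stack
#'
#' Projects one channel of a calibrated stack by taking, per pixel, the
#' maximum over all z-slices. This is the projection convention used for
#' whole-cluster overviews (e.g. counting polarised clusters).
#'
#' @param stack a [calibrated_stack()].
#' @param channel channel name or index.
#' @return A [projected_image()] whose provenance records the full slice
#'   range.
#' @export
max_project_full <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "calibrated_stack"))
  ch <- channel_index(stack, channel)
  v <- stack$voxels[, , , ch, drop = FALSE]
  nz <- dim(v)[3L]
  if (nz < 1L) stop_amis("amisquant_precondition_error", "stack has no slices")
  out <- apply(v[, , , 1L, drop = TRUE], c(1L, 2L), max)
  if (nz == 1L) out <- v[, , 1L, 1L]
  projected_image(out, stack$pixel_size_um,
                  channel = stack$channel_names[ch],
                  provenance = list(method = "max_project_full",
                                    slices = seq_len(nz)))
}

## 1-based indices of the three central slices of an n-slice stack
central_slice_set <- function(nz) {
  centre <- nz %/% 2L + 1L        # for odd n this is ceiling(n/2)
  slices <- (centre - 1L):(centre + 1L)
  if (slices[3L] > nz) slices <- slices - 1L
  slices
}

#' Maximum-value projection of the three central z-slices
#'
#' Projects the three central slices only, the convention used for
#' line-scans and region-of-interest measurements (a "central section"
#' image). For a stack of `n` slices the centre slice is `ceiling(n / 2)`
#' for odd `n`; for even `n` the slice `n / 2 + 1` with its two neighbours
#' is used (i.e. 1-based indices `{floor(n/2), floor(n/2)+1, floor(n/2)+2}`).
#' The slice set used is recorded in the provenance.
#'
#' @inheritParams max_project_full
#' @return A [projected_image()].
#' @export
central_section_project <- function(stack, channel = 1L) {
  stopifnot(inherits(stack, "calibrated_stack"))
  ch <- channel_index(stack, channel)
  nz <- dim(stack$voxels)[3L]
  if (nz < 3L)
    stop_amis("amisquant_precondition_error",
              "central-section projection needs >= 3 slices, got %d", nz)
  slices <- central_slice_set(nz)
  v <- stack$voxels[, , slices, ch, drop = TRUE]
  out <- apply(v, c(1L, 2L), max)
  if (is.null(dim(out))) out <- v  # defensive; slices is always length 3
  projected_image(out, stack$pixel_size_um,
                  channel = stack$channel_names[ch],
                  provenance = list(method = "central_section_project",
                                    slices = slices))
}
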