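#' Input-gradient saliency map
#'
#' Absolute gradient of the network's pre-sigmoid output (the sigmoid head
#' is exchanged for a linear one, which sharpens the map) with respect to
#' one input matrix, evaluated with batch normalisation in inference mode.
#' Large entries mark cells where small input changes most affect the
#' prediction.
#'
#' @param net a trained `introscan_cnn`.
#' @param mat a [resized_matrix()] or a bins x columns matrix of the
#'   network's input shape.
#' @return non-negative matrix of the same shape as the input.
#' @export
saliency_map <- function(net, mat) {
  if (inherits(mat, "resized_matrix")) mat <- mat$mat
  stopifnot(all(dim(mat) == net$input_shape))
  xb <- matrix(as.numeric(mat), ncol = 1)
  fw <- .net_forward(net, xb, train = FALSE)
  bw <- .net_backward(net, fw$caches, 1, train = FALSE)
  matrix(abs(bw$dx), nrow(mat), ncol(mat))
}

#' Scenario-averaged saliency maps
#'
#' Element-wise mean of per-input saliency maps over a set of matrices per
#' scenario (300 per scenario at reporting scale).
#'
#' @param net a trained `introscan_cnn`.
#' @param matrix_sets named list (scenario -> list of matrices).
#' @return named list of mean saliency matrices.
#' @export
average_saliency <- function(net, matrix_sets) {
  stopifnot(length(matrix_sets) >= 1)
  lapply(matrix_sets, function(set) {
    stopifnot(length(set) >= 1)
    acc <- NULL
    for (m in set) {
      s <- saliency_map(net, m)
      acc <- if (is.null(acc)) s else acc + s
    }
    acc / length(set)
  })
}

#' Per-population attention mass of a saliency map
#'
#' Sums saliency over the columns of each population block, as a simple
#' summary of where the network's attention concentrates.
#'
#' @param sal saliency matrix (bins x columns).
#' @param blocks named list of column index ranges ([resized_matrix()]
#'   `$blocks`).
#' @return named numeric vector of block sums.
#' @export
saliency_block_mass <- function(sal, blocks) {
  vapply(blocks, function(ii) sum(sal[, ii]), 0)
}
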