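# Fusion operators used to join the chemical and target-based modalities:
# the augmented outer product, the tensor fusion layer (TFL), multimodal
# circulant fusion (MCF), and elementwise/concatenation fusion.

#' Augmented outer product of two representation vectors
#'
#' Computes the outer product of the two input vectors after appending a
#' constant 1 to each: `x_f = [f1; 1] (x) [f2; 1]`. The resulting
#' `(p+1) x (q+1)` matrix carries three kinds of information at once: the
#' top-left `p x q` block holds every pairwise (bimodal) product
#' `f1[i] * f2[j]`, the last column holds `f1` itself, and the last row holds
#' `f2`, with a constant 1 in the corner. It is the input representation of
#' the OPCNN classifier and of the tensor fusion layer.
#'
#' @param f1,f2 Finite numeric vectors (the two modality representations;
#'   by convention length 50 each inside the networks, but any positive
#'   lengths are accepted).
#' @return A numeric matrix of dimension `(length(f1)+1) x (length(f2)+1)`
#'   with class `"fused_tensor"` and attributes `p` and `q` recording the
#'   input lengths.
#' @seealso [tfl_fuse()] for the flattened form, [build_opcnn()] for the
#'   classifier that consumes it.
#' @examples
#' augmented_outer_product(c(1, 0), c(0, 2))
#' @export
augmented_outer_product <- function(f1, f2) {
  check_numeric_vector(f1, "f1")
  check_numeric_vector(f2, "f2")
  a1 <- c(as.numeric(f1), 1)
  a2 <- c(as.numeric(f2), 1)
  m <- outer(a1, a2)
  structure(m, class = c("fused_tensor", class(m)),
            p = length(f1), q = length(f2))
}

#' Circulant matrix of a vector
#'
#' Builds the `d x d` circulant matrix whose first column equals `b` and in
#' which every subsequent column is the previous one cyclically shifted down
#' by one, i.e. `A[i, j] = b[((i - j) mod d) + 1]`. This is the standard
#' circulant convention; the transposed convention is available via
#' `direction = "up"`.
#'
#' @param b Finite numeric vector of length `d >= 1`.
#' @param direction `"down"` (default, first column equals `b`) or `"up"`
#'   (the transpose, first row equals `b`).
#' @return A `d x d` numeric matrix.
#' @examples
#' circulant(c(1, 2, 3))
#' @export
circulant <- function(b, direction = c("down", "up")) {
  direction <- match.arg(direction)
  check_numeric_vector(b, "b")
  d <- length(b)
  shift <- outer(0:(d - 1), 0:(d - 1), `-`)
  a <- matrix(b[(shift %% d) + 1], d, d)
  if (direction == "up") t(a) else a
}

#' Circulant interaction step of multimodal circulant fusion
#'
#' Given two projected modality vectors `v` and `c` of equal length `d`,
#' forms the circulant matrices `A = circ(v)` and `B = circ(c)` and lets
#' every element of each vector interact with every element of the other.
#' Two parameter-free variants are supported:
#' \describe{
#'   \item{`matmul`}{`f = A c`, `g = B v` (full circulant matrix product).}
#'   \item{`avg_elementwise`}{`f = (1/d) sum_i a_i * c`,
#'     `g = (1/d) sum_i b_i * v`, where `a_i`, `b_i` are the columns of `A`
#'     and `B` and `*` is the elementwise product. Because every row of a
#'     circulant matrix contains each entry of the generating vector exactly
#'     once, the column average collapses to `f = mean(v) * c`,
#'     `g = mean(c) * v`; the closed form is used but tests pin it to the
#'     explicit column-sum definition.}
#' }
#' Neither variant introduces learnable parameters.
#'
#' @param v,c Finite numeric vectors of equal length.
#' @param variant `"matmul"` or `"avg_elementwise"`.
#' @return A list with numeric vectors `f` and `g`.
#' @examples
#' mcf_interact(c(1, 2), c(3, 4), "matmul")          # f = c(11, 10)
#' mcf_interact(c(1, 2), c(3, 4), "avg_elementwise") # f = c(4.5, 6)
#' @export
mcf_interact <- function(v, c, variant = c("matmul", "avg_elementwise")) {
  variant <- match.arg(variant)
  check_numeric_vector(v, "v")
  check_numeric_vector(c, "c")
  if (length(v) != length(c)) {
    opcnn_stop("`v` and `c` must have the same length", "dimension_error")
  }
  if (variant == "matmul") {
    f <- as.numeric(circulant(v) %*% c)
    g <- as.numeric(circulant(c) %*% v)
  } else {
    f <- mean(v) * c
    g <- mean(c) * v
  }
  list(f = f, g = g)
}

#' Parameters for multimodal circulant fusion
#'
#' Creates the three projection matrices of MCF: `W1, W2` project the two
#' 50-dimensional representation vectors to dimension `d <= 50`, and `W3`
#' maps the fused interaction vector to the `k`-dimensional output
#' `m = W3 (f + g)`. Inside a network the three matrices are trainable;
#' initial values are drawn from a fan-in-scaled normal under `seed`.
#'
#' @param d Projection dimension (`1 <= d <= in_dim`).
#' @param k Output dimension.
#' @param in_dim Length of the incoming representation vectors (default 50).
#' @param variant Interaction variant passed to [mcf_interact()].
#' @param seed RNG seed for the initial matrices.
#' @return A list with matrices `W1`, `W2` (`d x in_dim`), `W3` (`k x d`),
#'   the dimensions, and the variant, of class `"mcf_params"`.
#' @export
mcf_params <- function(d = 50L, k = 50L, in_dim = 50L,
                       variant = c("matmul", "avg_elementwise"), seed = 1L) {
  variant <- match.arg(variant)
  d <- as.integer(d); k <- as.integer(k); in_dim <- as.integer(in_dim)
  if (d < 1L || k < 1L || in_dim < 1L || d > in_dim) {
    opcnn_stop("mcf_params requires 1 <= d <= in_dim and k >= 1",
               "config_error")
  }
  with_seed(seed, {
    sd_in <- sqrt(1 / in_dim)
    structure(list(
      W1 = matrix(stats::rnorm(d * in_dim, sd = sd_in), d, in_dim),
      W2 = matrix(stats::rnorm(d * in_dim, sd = sd_in), d, in_dim),
      W3 = matrix(stats::rnorm(k * d, sd = sqrt(1 / d)), k, d),
      d = d, k = k, in_dim = in_dim, variant = variant
    ), class = "mcf_params")
  })
}

#' Multimodal circulant fusion
#'
#' Full MCF pipeline: project both representation vectors
#' (`v = W1 f1`, `c = W2 f2`), let them interact through circulant matrices
#' ([mcf_interact()]), and project the elementwise sum of the two
#' interaction vectors to the output, `m = W3 (f + g)`.
#'
#' @param f1,f2 Numeric vectors of length `params$in_dim`.
#' @param params An [mcf_params()] object.
#' @param variant Optional override of `params$variant`.
#' @return Numeric vector of length `params$k`.
#' @export
mcf_fuse <- function(f1, f2, params, variant = NULL) {
  if (!inherits(params, "mcf_params")) {
    opcnn_stop("`params` must be created by mcf_params()", "config_error")
  }
  check_numeric_vector(f1, "f1")
  check_numeric_vector(f2, "f2")
  if (length(f1) != params$in_dim || length(f2) != params$in_dim) {
    opcnn_stop(sprintf("mcf_fuse expects inputs of length %d", params$in_dim),
               "dimension_error")
  }
  variant <- variant %||% params$variant
  v <- as.numeric(params$W1 %*% f1)
  cc <- as.numeric(params$W2 %*% f2)
  fg <- mcf_interact(v, cc, variant)
  as.numeric(params$W3 %*% (fg$f + fg$g))
}

#' Elementwise and concatenation fusion
#'
#' The three simple fusion operations: elementwise `addition`, elementwise
#' `product`, and `concatenation`. Addition and product require equal
#' lengths; concatenation accepts any lengths and returns `c(f1, f2)`.
#'
#' @param mode One of `"addition"`, `"product"`, `"concatenation"`.
#' @param f1,f2 Finite numeric vectors.
#' @return Numeric vector.
#' @export
simple_fusion <- function(mode = c("addition", "product", "concatenation"),
                          f1, f2) {
  mode <- match.arg(mode)
  check_numeric_vector(f1, "f1")
  check_numeric_vector(f2, "f2")
  if (mode != "concatenation" && length(f1) != length(f2)) {
    opcnn_stop(sprintf("fusion mode '%s' requires equal lengths", mode),
               "dimension_error")
  }
  switch(mode,
         addition = f1 + f2,
         product = f1 * f2,
         concatenation = c(f1, f2))
}

#' Tensor fusion layer
#'
#' Fusion by the same augmented outer product as
#' [augmented_outer_product()], flattened row-major into a vector of length
#' `(p+1)(q+1)` so that a dense layer can consume it. The flattening order
#' is immaterial to a following dense layer but is pinned (row-major) for
#' reproducibility. TFL introduces no learnable parameters.
#'
#' @inheritParams augmented_outer_product
#' @return Numeric vector of length `(length(f1)+1) * (length(f2)+1)`.
#' @export
tfl_fuse <- function(f1, f2) {
  m <- augmented_outer_product(f1, f2)
  as.numeric(t(unclass(m)))
}
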