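#' Specification for a synthetic microarray-like dataset
#'
#' Describes an imbalanced, high-dimensional expression dataset: few
#' samples, many genes, a small informative subset carrying class
#' structure, the rest pure noise. Three structures are available:
#' \describe{
#'   \item{linear}{classes differ by mean shifts on the informative genes
#'     (separable by a linear kernel);}
#'   \item{radial}{classes sit at different radii of a latent subspace, so
#'     class identity is carried by distance from the origin rather than
#'     direction — a geometry a linear kernel cannot separate;}
#'   \item{mixed}{half the informative genes carry the linear structure,
#'     half the radial one.}
#' }
#'
#' @param class_sizes Integer vector of per-class sample counts (>= 1 each).
#' @param n_genes Total gene count.
#' @param n_informative Number of class-informative genes
#'   (`<= n_genes`).
#' @param effect_size Class-mean separation in units of `noise_sd`;
#'   0 removes all structure.
#' @param structure `"linear"`, `"radial"` or `"mixed"`.
#' @param noise_sd Standard deviation of the Gaussian noise, default 1.
#' @param seed Integer seed.
#' @param diffuse_classes Optional integer codes (0-based) of classes
#'   generated without informative structure (noise-only "other" groups).
#' @return A `synth_spec` list.
#' @export
synth_spec <- function(class_sizes, n_genes, n_informative,
                       effect_size, structure = c("linear", "radial", "mixed"),
                       noise_sd = 1, seed = 1, diffuse_classes = integer(0)) {
  structure_kind <- match.arg(structure)
  if (n_informative > n_genes) stop("n_informative must be <= n_genes")
  if (any(class_sizes < 1)) stop("every class needs at least one sample")
  if (effect_size < 0) stop("effect_size must be >= 0")
  if (noise_sd <= 0) stop("noise_sd must be > 0")
  structure(
    list(class_sizes = as.integer(class_sizes), n_genes = as.integer(n_genes),
         n_informative = as.integer(n_informative), effect_size = effect_size,
         structure = structure_kind, noise_sd = noise_sd, seed = as.integer(seed),
         diffuse_classes = as.integer(diffuse_classes)),
    class = "synth_spec"
  )
}

# class-mean matrix (C x n_inf) for the linear structure: independent
# Gaussian mean profiles scaled so expected pairwise separation is
# effect_size * sqrt(2 * n_inf) * noise_sd
linear_class_means <- function(C, n_inf, effect, noise_sd) {
  matrix(rnorm(C * n_inf, sd = effect * noise_sd), C, n_inf)
}

# classes live on concentric rings of a 2-D latent plane embedded across
# the radial genes: low latent dimension keeps the shells learnable from
# tens of samples, while zero class means defeat any linear separator
radial_basis <- function(p) {
  qr.Q(qr(matrix(rnorm(p * min(2L, p)), p)))[, seq_len(min(2L, p)), drop = FALSE]
}

radial_block <- function(n, radius, noise_sd, basis) {
  latent <- ncol(basis)
  u <- matrix(rnorm(n * latent), n, latent)
  u <- u / pmax(sqrt(rowSums(u^2)), .Machine$double.eps)
  (radius * u) %*% t(basis) +
    matrix(rnorm(n * nrow(basis), sd = noise_sd), n, nrow(basis))
}

#' Generate a synthetic expression dataset
#'
#' Draws the dataset described by a [synth_spec()]: informative genes carry
#' the class structure, the remaining genes are Gaussian noise, and the
#' whole matrix is affinely shifted into a positive, expression-like range
#' (min-max normalization later erases location and scale, so only the
#' geometry matters).
#'
#' @param spec A `synth_spec`.
#' @return An [expression_matrix()] with `sum(class_sizes)` samples.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "synth_spec"))
  C <- length(spec$class_sizes)
  M <- sum(spec$class_sizes)
  labels <- rep(seq_len(C) - 1L, spec$class_sizes)
  withr::with_seed(spec$seed, {
    X <- matrix(rnorm(M * spec$n_genes, sd = spec$noise_sd), M, spec$n_genes)
    n_inf <- spec$n_informative
    if (n_inf > 0 && spec$effect_size > 0) {
      n_lin <- switch(spec$structure, linear = n_inf, radial = 0L,
                      mixed = n_inf %/% 2L)
      n_rad <- n_inf - n_lin
      informative <- !(seq_len(C) - 1L) %in% spec$diffuse_classes
      if (n_lin > 0) {
        mu <- linear_class_means(C, n_lin, spec$effect_size, spec$noise_sd)
        mu[!informative, ] <- 0
        X[, seq_len(n_lin)] <- X[, seq_len(n_lin)] + mu[labels + 1L, , drop = FALSE]
      }
      if (n_rad > 0) {
        cols <- n_lin + seq_len(n_rad)
        radii <- spec$effect_size * spec$noise_sd * (1 + 2 * (seq_len(C) - 1))
        basis <- radial_basis(n_rad)
        for (c in seq_len(C)) {
          rows <- which(labels == c - 1L)
          if (!informative[c]) next
          X[rows, cols] <- radial_block(length(rows), radii[c], spec$noise_sd, basis)
        }
      }
    }
    X <- X - min(X) + 1  # expression-like positive range
    rownames(X) <- paste0("sample_", seq_len(M))
    colnames(X) <- paste0("gene_", seq_len(spec$n_genes))
    expression_matrix(X, labels, class_names = paste0("class_", seq_len(C) - 1L))
  })
}

paperlike_shapes <- list(
  colon = list(class_sizes = c(40L, 22L), n_genes = 2000L,
               diffuse_classes = integer(0)),
  aml_all = list(class_sizes = c(47L, 25L), n_genes = 7129L,
                 diffuse_classes = integer(0)),
  st_jude = list(class_sizes = c(9L, 18L, 42L, 14L, 28L, 52L, 52L),
                 n_genes = 12558L, diffuse_classes = 6L),
  lung = list(class_sizes = c(139L, 21L, 20L, 6L, 17L), n_genes = 3312L,
              diffuse_classes = integer(0))
)

#' Synthetic dataset shaped like the benchmark microarray studies
#'
#' Emulates the sample/gene/class geometry of four classic cancer
#' microarray benchmarks: Colon (62 samples x 2000 genes, 2 classes),
#' AML-ALL leukemia (72 x 7129, classes 47/25), St. Jude leukemia
#' (215 x 12558, 7 classes 9/18/42/14/28/52/52, the last a diffuse
#' catch-all group generated without informative structure), and Lung
#' (203 x 3312, 5 classes 139/21/20/6/17). The data themselves are
#' synthetic draws from [generate_dataset()] — only the shapes and
#' imbalance follow the originals.
#'
#' @param name `"colon"`, `"aml_all"`, `"st_jude"` or `"lung"`.
#' @param scale Factor in (0, 1] applied to class sizes and gene counts
#'   (floored, minimum 2 samples per class and 20 genes) to build
#'   smaller replicas of the same geometry.
#' @param effect_size Class separation, default 3 (clearly separable
#'   informative signal).
#' @param structure Class geometry, default `"linear"`.
#' @param n_informative Informative gene count; default 5% of genes,
#'   at least 10.
#' @param seed Integer seed.
#' @return An [expression_matrix()].
#' @export
paperlike <- function(name = c("colon", "aml_all", "st_jude", "lung"),
                      scale = 1, effect_size = 3,
                      structure = "linear", n_informative = NULL, seed = 1) {
  name <- match.arg(name)
  if (scale <= 0 || scale > 1) stop("scale must be in (0, 1]")
  shape <- paperlike_shapes[[name]]
  class_sizes <- pmax(2L, as.integer(floor(scale * shape$class_sizes)))
  n_genes <- max(20L, as.integer(floor(scale * shape$n_genes)))
  if (is.null(n_informative)) {
    n_informative <- max(10L, as.integer(ceiling(0.05 * n_genes)))
  }
  n_informative <- min(n_informative, n_genes)
  generate_dataset(synth_spec(
    class_sizes = class_sizes, n_genes = n_genes,
    n_informative = n_informative, effect_size = effect_size,
    structure = structure, seed = seed,
    diffuse_classes = shape$diffuse_classes
  ))
}
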