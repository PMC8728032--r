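#' Compound-symmetry covariance matrix
#'
#' Builds the exchangeable covariance matrix with unit variances and a single
#' common correlation `rho`: ones on the diagonal, `rho` everywhere else.
#' This is the correlation structure used throughout the simulation settings
#' (`rho = 0.1` for the weakly correlated matrix, `rho = 0.5` for the
#' moderately correlated one).
#'
#' @param p Dimension (number of variables), a positive integer.
#' @param rho Common off-diagonal correlation. Positive definiteness requires
#'   `-1/(p - 1) < rho < 1`.
#' @return A `p x p` numeric matrix.
#' @examples
#' compound_symmetry_cov(4, 0.3)
#' @export
compound_symmetry_cov <- function(p, rho) {
  if (length(p) != 1L || p < 1 || p != round(p)) {
    abort("`p` must be a single positive integer.")
  }
  p <- as.integer(p)
  lower <- if (p > 1) -1 / (p - 1) else -1
  if (length(rho) != 1L || !is.finite(rho) || rho <= lower || rho >= 1) {
    abort(sprintf(
      "`rho` must lie in (%.6g, 1) for positive definiteness at p = %d (got %g).",
      lower, p, rho
    ))
  }
  sigma <- matrix(rho, p, p)
  diag(sigma) <- 1
  sigma
}

#' Mixture component specification
#'
#' One component of a multivariate mixture distribution: either a
#' multivariate normal or a multivariate Student-t. For the t family the
#' `scale` matrix is the *scale* parameter of the distribution, not its
#' covariance; with `df` degrees of freedom the covariance is
#' `df / (df - 2) * scale` (so 3 times the scale at the heavy-tailed
#' `df = 3` used to model expression heterogeneity).
#'
#' @param family `"normal"` or `"student_t"`.
#' @param mean Length-`p` mean vector.
#' @param scale `p x p` symmetric positive-definite scale matrix.
#' @param weight Mixing proportion in `[0, 1]`.
#' @param df Degrees of freedom (Student-t only; must be >= 1).
#' @return An object of class `mixture_component`.
#' @export
mixture_component <- function(family = c("normal", "student_t"), mean, scale,
                              weight = 1, df = NULL) {
  family <- match.arg(family)
  mean <- as.numeric(mean)
  scale <- as.matrix(scale)
  p <- length(mean)
  if (!identical(dim(scale), c(p, p))) {
    abort("`scale` must be a square matrix matching length(mean).")
  }
  if (max(abs(scale - t(scale))) > 1e-8) {
    abort("`scale` must be symmetric.")
  }
  if (weight < 0 || weight > 1) {
    abort("`weight` must lie in [0, 1].")
  }
  if (family == "student_t") {
    if (is.null(df) || df < 1) {
      abort("`df` must be >= 1 for the student_t family.")
    }
    df <- as.numeric(df)
  } else {
    df <- NULL
  }
  structure(
    list(family = family, mean = mean, scale = scale, weight = weight, df = df),
    class = "mixture_component"
  )
}

# Cholesky factor with a clear error for non-PD scales.
component_chol <- function(comp) {
  ch <- tryCatch(chol(comp$scale), error = function(e) NULL)
  if (is.null(ch)) {
    abort("Component scale matrix is not positive definite; Cholesky decomposition failed.")
  }
  ch
}

# One i.i.d. block from a single component (n x p).
draw_component <- function(comp, n, chol_scale = component_chol(comp)) {
  p <- length(comp$mean)
  z <- matrix(rnorm(n * p), n, p) %*% chol_scale
  if (comp$family == "student_t") {
    w <- sqrt(comp$df / rchisq(n, df = comp$df))
    z <- z * w
  }
  sweep(z, 2, comp$mean, "+")
}

#' Sample from a multivariate mixture
#'
#' Draws `n` i.i.d. rows from a finite mixture of multivariate normal and/or
#' Student-t components. Each row first samples a component index by the
#' mixing weights and then draws from that component, so the weights act as
#' probabilities rather than deterministic quotas.
#'
#' @param components A list of [mixture_component()] objects whose weights
#'   sum to 1 (within `1e-12`).
#' @param n Number of rows to draw.
#' @param seed Optional integer seed; the same seed reproduces the draw
#'   exactly and the caller's RNG state is restored afterwards.
#' @return An `n x p` numeric matrix.
#' @export
sample_mixture <- function(components, n, seed = NULL) {
  if (inherits(components, "mixture_component")) {
    components <- list(components)
  }
  stopifnot(length(components) >= 1, n >= 1)
  w <- vapply(components, function(c) c$weight, numeric(1))
  if (abs(sum(w) - 1) > 1e-12) {
    abort(sprintf("Component weights must sum to 1 (got %.15g).", sum(w)))
  }
  p <- length(components[[1]]$mean)
  for (comp in components) {
    if (length(comp$mean) != p) abort("All components must share one dimension p.")
  }
  chols <- lapply(components, component_chol)
  with_seed(seed, {
    out <- matrix(NA_real_, n, p)
    if (length(components) == 1L) {
      out[] <- draw_component(components[[1]], n, chols[[1]])
    } else {
      idx <- sample.int(length(components), n, replace = TRUE, prob = w)
      for (k in seq_along(components)) {
        rows <- which(idx == k)
        if (length(rows)) {
          out[rows, ] <- draw_component(components[[k]], length(rows), chols[[k]])
        }
      }
    }
    out
  })
}

#' Two-group multivariate dataset
#'
#' Container for a control-group and a case-group sample over the same `p`
#' variables, the universal input of the gene-set analysis tests.
#'
#' @param x_control,x_case Numeric matrices (samples x variables) with equal
#'   column counts.
#' @param seed Optional integer recording the seed the data were drawn under.
#' @return An object of class `two_group_dataset`.
#' @export
two_group_dataset <- function(x_control, x_case, seed = NULL) {
  x_control <- as_sample_matrix(x_control, "x_control")
  x_case <- as_sample_matrix(x_case, "x_case")
  if (ncol(x_control) != ncol(x_case)) {
    abort("Control and case matrices must have the same number of variables.")
  }
  structure(
    list(x_control = x_control, x_case = x_case, seed = seed),
    class = "two_group_dataset"
  )
}

#' @export
print.two_group_dataset <- function(x, ...) {
  cat(sprintf(
    "<two_group_dataset> %d control + %d case samples, %d variables\n",
    nrow(x$x_control), nrow(x$x_case), ncol(x$x_control)
  ))
  invisible(x)
}

# Pooled samples-x-variables matrix and 0/1 labels (control = 0, case = 1).
pool_two_group <- function(data) {
  list(
    x = rbind(data$x_control, data$x_case),
    y = c(rep(0L, nrow(data$x_control)), rep(1L, nrow(data$x_case)))
  )
}

setting_ids <- function() c("A", "B", "C", "D", "E", "F", "G", "H")

#' Simulation setting specification
#'
#' Builds the per-group mixture specification for one of the eight benchmark
#' settings A-H. Settings A/B are single-component (normal / t with 3 df);
#' C/D are 2-component mixtures in both groups (components centred at 0 and
#' 1, with the weakly and moderately correlated covariances respectively);
#' E/F and G/H model disease subtypes: a single-component control group
#' against a 2- or 3-component case mixture whose components are shifted by
#' 0, `delta / 2` and `delta`. `delta = 0` collapses every case mixture onto
#' its control distribution.
#'
#' @param setting_id One of `"A"`..`"H"`.
#' @param delta Common per-variable mean shift `>= 0` between case and
#'   control.
#' @param n_per_group Samples per group (default 50).
#' @param p Dimension (default 30).
#' @param rho1,rho2 Correlations of the two compound-symmetry matrices
#'   (defaults 0.1 and 0.5).
#' @param df Degrees of freedom of the Student-t components (default 3).
#' @return An object of class `simulation_setting` with fields `setting_id`,
#'   `control`, `case` (lists of [mixture_component()]), `delta`, `p`,
#'   `n_per_group`, `rho1`, `rho2`.
#' @export
simulation_setting <- function(setting_id, delta = 0, n_per_group = 50, p = 30,
                               rho1 = 0.1, rho2 = 0.5, df = 3) {
  setting_id <- as.character(setting_id)
  if (!setting_id %in% setting_ids()) {
    abort(sprintf(
      "Unknown setting_id '%s'; must be one of %s.",
      setting_id, paste(setting_ids(), collapse = ", ")
    ))
  }
  if (delta < 0) abort("`delta` must be >= 0.")
  s1 <- compound_symmetry_cov(p, rho1)
  s2 <- compound_symmetry_cov(p, rho2)
  zero <- rep(0, p)
  ones <- rep(1, p)
  dvec <- rep(delta, p)
  fam <- if (setting_id %in% c("A", "C", "E", "G")) "normal" else "student_t"
  tdf <- if (fam == "student_t") df else NULL
  comp <- function(mean, scale, weight) {
    mixture_component(fam, mean = mean, scale = scale, weight = weight, df = tdf)
  }
  spec <- switch(setting_id,
    A = ,
    B = {
      sc <- if (setting_id == "A") s1 else s2
      list(
        control = list(comp(zero, sc, 1)),
        case = list(comp(dvec, sc, 1))
      )
    },
    C = ,
    D = list(
      control = list(comp(zero, s1, 0.5), comp(ones, s2, 0.5)),
      case = list(comp(dvec, s1, 0.5), comp(ones + dvec, s2, 0.5))
    ),
    E = ,
    F = {
      sc <- if (setting_id == "E") s1 else s2
      list(
        control = list(comp(zero, sc, 1)),
        case = list(comp(zero, sc, 0.5), comp(dvec, sc, 0.5))
      )
    },
    G = ,
    H = {
      sc <- if (setting_id == "G") s1 else s2
      list(
        control = list(comp(zero, sc, 1)),
        case = list(
          comp(zero, sc, 0.4),
          comp(0.5 * dvec, sc, 0.3),
          comp(dvec, sc, 0.3)
        )
      )
    }
  )
  structure(
    list(
      setting_id = setting_id, control = spec$control, case = spec$case,
      delta = delta, p = as.integer(p), n_per_group = as.integer(n_per_group),
      rho1 = rho1, rho2 = rho2
    ),
    class = "simulation_setting"
  )
}

#' Generate a two-group dataset from a benchmark setting
#'
#' Draws `n_per_group` control and `n_per_group` case samples from the
#' mixture distributions of the requested setting.
#'
#' @param setting_id One of `"A"`..`"H"`, or a [simulation_setting()] object
#'   (in which case `delta`, `n_per_group`, `p` are taken from it).
#' @inheritParams simulation_setting
#' @param seed Optional integer seed for an exactly reproducible draw.
#' @return A [two_group_dataset()].
#' @examples
#' d <- generate_setting("A", delta = 0.3, seed = 1)
#' dim(d$x_case)
#' @export
generate_setting <- function(setting_id, delta = 0, n_per_group = 50, p = 30,
                             seed = NULL, rho1 = 0.1, rho2 = 0.5, df = 3) {
  setting <- if (inherits(setting_id, "simulation_setting")) {
    setting_id
  } else {
    simulation_setting(setting_id, delta, n_per_group, p, rho1, rho2, df)
  }
  n <- setting$n_per_group
  with_seed(seed, {
    xc <- sample_mixture(setting$control, n)
    xt <- sample_mixture(setting$case, n)
    two_group_dataset(xc, xt, seed = seed)
  })
}

#' Synthetic expression dataset container
#'
#' A genes-by-samples expression matrix with identifiers, optional binary
#' labels and a named gene-set collection. On disk the matrix is stored
#' genes x samples; the multivariate tests operate on its samples x genes
#' transpose, extracted per gene set.
#'
#' @param mat Numeric genes x samples matrix.
#' @param gene_ids,sample_ids Unique identifier vectors matching the matrix
#'   dimensions.
#' @param labels Optional 0/1 vector, one per sample.
#' @param gene_sets Named list of character vectors of gene ids. Members not
#'   present in `gene_ids` are tolerated and resolved at use.
#' @return An object of class `expression_dataset`.
#' @export
expression_dataset <- function(mat, gene_ids = rownames(mat),
                               sample_ids = colnames(mat), labels = NULL,
                               gene_sets = list()) {
  mat <- as.matrix(mat)
  storage.mode(mat) <- "double"
  gene_ids <- as.character(gene_ids)
  sample_ids <- as.character(sample_ids)
  if (nrow(mat) != length(gene_ids)) {
    abort("`gene_ids` must have one entry per matrix row.")
  }
  if (ncol(mat) != length(sample_ids)) {
    abort("`sample_ids` must have one entry per matrix column.")
  }
  if (anyDuplicated(gene_ids)) abort("`gene_ids` must be unique.")
  if (anyDuplicated(sample_ids)) abort("`sample_ids` must be unique.")
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != ncol(mat) || !all(labels %in% c(0L, 1L))) {
      abort("`labels` must be a 0/1 vector with one entry per sample.")
    }
  }
  rownames(mat) <- gene_ids
  colnames(mat) <- sample_ids
  structure(
    list(
      matrix = mat, gene_ids = gene_ids, sample_ids = sample_ids,
      labels = labels, gene_sets = gene_sets
    ),
    class = "expression_dataset"
  )
}

#' @export
print.expression_dataset <- function(x, ...) {
  cat(sprintf(
    "<expression_dataset> %d genes x %d samples, %d gene set(s)%s\n",
    length(x$gene_ids), length(x$sample_ids), length(x$gene_sets),
    if (is.null(x$labels)) "" else ", labelled"
  ))
  invisible(x)
}

#' Extract the samples-x-genes matrix of one gene set
#'
#' Resolves a gene set against the dataset's gene ids (exact string match)
#' and returns the transposed submatrix ready for the multivariate tests.
#'
#' @param expr An [expression_dataset()].
#' @param genes Character vector of gene ids, or the name of a set in
#'   `expr$gene_sets`.
#' @return A samples x genes numeric matrix.
#' @export
expression_subset <- function(expr, genes) {
  stopifnot(inherits(expr, "expression_dataset"))
  if (length(genes) == 1L && genes %in% names(expr$gene_sets)) {
    genes <- expr$gene_sets[[genes]]
  }
  present <- intersect(genes, expr$gene_ids)
  if (length(present) == 0L) {
    abort("None of the requested genes are present in the dataset.")
  }
  t(expr$matrix[present, , drop = FALSE])
}

#' Split an expression dataset into a two-group dataset
#'
#' @inheritParams expression_subset
#' @return A [two_group_dataset()] with group 0 as control and group 1 as
#'   case, restricted to `genes` (all genes when `NULL`).
#' @export
as_two_group_dataset <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "expression_dataset"))
  if (is.null(expr$labels)) abort("Dataset has no labels.")
  x <- if (is.null(genes)) t(expr$matrix) else expression_subset(expr, genes)
  two_group_dataset(
    x[expr$labels == 0L, , drop = FALSE],
    x[expr$labels == 1L, , drop = FALSE]
  )
}

#' Generate a synthetic expression dataset
#'
#' Builds a labelled genes x samples expression matrix in which the genes of
#' each declared set share a correlated (optionally mixture) multivariate
#' structure while background genes are i.i.d. This stands in for a real
#' normalized expression matrix so that the rejection-rate protocol and the
#' GSA tests can be exercised end-to-end.
#'
#' Genes of set `k` are drawn, per sample group, from the mixture
#' specification in `group_models[[k]]` (a [simulation_setting()] restricted
#' to the set's size); when no model is supplied, both groups are drawn from
#' a single multivariate normal with compound-symmetry correlation `rho`.
#' The `marginal` argument then maps the draws through a marginal transform:
#' `"normal"` leaves them, `"lognormal"` exponentiates (a strong, realistic
#' violation of multivariate normality), `"t"` rescales to heavy Student-t
#' tails with 3 df.
#'
#' @param n_genes Total number of genes.
#' @param n_samples_per_group Samples in each of the two groups.
#' @param gene_set_sizes Integer vector of declared set sizes (each
#'   `<= n_genes`).
#' @param group_models Optional list (recycled) of [simulation_setting()]
#'   objects, one per set, giving each set's per-group distributions.
#' @param marginal `"normal"`, `"lognormal"` or `"t"`.
#' @param rho Within-set correlation when no `group_models` given.
#' @param seed Integer seed; identical seeds give byte-identical datasets.
#' @return An [expression_dataset()] with labels (0 = control, 1 = case) and
#'   gene sets named `"set1"`, `"set2"`, ...
#' @export
generate_expression_dataset <- function(n_genes, n_samples_per_group,
                                        gene_set_sizes = integer(),
                                        group_models = NULL,
                                        marginal = c("normal", "lognormal", "t"),
                                        rho = 0.1, seed = NULL) {
  marginal <- match.arg(marginal)
  gene_set_sizes <- as.integer(gene_set_sizes)
  if (any(gene_set_sizes > n_genes)) {
    abort("Every gene_set_size must be <= n_genes.")
  }
  if (sum(gene_set_sizes) > n_genes) {
    abort("Declared gene sets exceed the total number of genes.")
  }
  n <- 2L * as.integer(n_samples_per_group)
  labels <- c(rep(0L, n_samples_per_group), rep(1L, n_samples_per_group))
  with_seed(seed, {
    x <- matrix(rnorm(n_genes * n), nrow = n_genes, ncol = n)
    gene_sets <- list()
    offset <- 0L
    for (k in seq_along(gene_set_sizes)) {
      s <- gene_set_sizes[k]
      rows <- offset + seq_len(s)
      offset <- offset + s
      if (!is.null(group_models)) {
        model <- group_models[[(k - 1L) %% length(group_models) + 1L]]
        sub <- simulation_setting(
          model$setting_id, model$delta,
          n_per_group = n_samples_per_group, p = s,
          rho1 = model$rho1, rho2 = model$rho2
        )
        block <- rbind(
          sample_mixture(sub$control, n_samples_per_group),
          sample_mixture(sub$case, n_samples_per_group)
        )
      } else {
        sigma <- compound_symmetry_cov(s, rho)
        block <- matrix(rnorm(n * s), n, s) %*% chol(sigma)
      }
      x[rows, ] <- t(block)
      gene_sets[[paste0("set", k)]] <- rows # filled with ids below
    }
    if (marginal == "lognormal") {
      x <- exp(x)
    } else if (marginal == "t") {
      x <- x * sqrt(3 / matrix(rchisq(n, df = 3), n_genes, n, byrow = TRUE))
    }
    gene_ids <- sprintf("GENE%04d", seq_len(n_genes))
    sample_ids <- sprintf("SAMPLE%03d", seq_len(n))
    gene_sets <- lapply(gene_sets, function(rows) gene_ids[rows])
    expression_dataset(x, gene_ids, sample_ids, labels, gene_sets)
  })
}
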