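#' Load a rooted time-calibrated tree from Newick text
#'
#' Parses a Newick string with branch lengths into an \code{ape} \code{phylo}
#' object and validates it for use as the source of a phylogenetic
#' correlation matrix: tip labels must be unique, branch lengths
#' non-negative, and the tree ultrametric (all root-to-tip path lengths
#' equal) within a relative tolerance of \code{tol}. Published supertrees
#' often carry small rounding slack in node ages, so an ultrametricity
#' violation beyond tolerance is a warning, not an error; downstream
#' correlation construction normalizes by the mean tip depth.
#'
#' @param newick_text Newick string (or path handled by the caller); must
#'   contain branch lengths.
#' @param tol relative tolerance on root-to-tip depth spread.
#' @return a \code{phylo} object.
#' @export
load_tree <- function(newick_text, tol = 1e-6) {
  tree <- tryCatch(
    ape::read.tree(text = newick_text),
    error = function(e) stop("malformed Newick: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("malformed Newick: parser returned no tree", call. = FALSE)
  validate_tree(tree, tol = tol)
  tree
}

#' Validate a phylogeny for covariance construction
#'
#' @param tree a \code{phylo} object.
#' @param tol relative ultrametricity tolerance.
#' @return the tree, invisibly.
#' @export
validate_tree <- function(tree, tol = 1e-6) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  if (is.null(tree$edge.length)) stop("tree has no branch lengths", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate tip labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(tree$edge.length < 0)) stop("negative branch lengths", call. = FALSE)
  dep <- tip_depths(tree)
  if (diff(range(dep)) > tol * mean(dep)) {
    warning(sprintf(
      "tree is not ultrametric within tolerance (depth range %.3g-%.3g); depths will be mean-normalized",
      min(dep), max(dep)), call. = FALSE)
  }
  invisible(tree)
}

#' Root-to-tip path lengths
#'
#' @param tree a \code{phylo} object.
#' @return named numeric vector of tip depths in the tree's time units.
#' @export
tip_depths <- function(tree) {
  dep <- ape::node.depth.edgelength(tree)[seq_along(tree$tip.label)]
  names(dep) <- tree$tip.label
  dep
}

#' Age of the most recent common ancestor of a set of tips
#'
#' Measured backwards from the present (tips at age 0), in the tree's time
#' units.
#'
#' @param tree a \code{phylo} object (assumed ultrametric).
#' @param tips character vector of tip labels.
#' @return the MRCA node age.
#' @export
mrca_age <- function(tree, tips) {
  stopifnot(all(tips %in% tree$tip.label))
  depth <- max(tip_depths(tree))
  node <- if (length(tips) == 1L) {
    match(tips, tree$tip.label)
  } else {
    ape::getMRCA(tree, tips)
  }
  node_depth <- ape::node.depth.edgelength(tree)[node]
  depth - node_depth
}

#' Graft a new tip as the sister of an existing tip at a calibrated age
#'
#' Splits the terminal branch leading to \code{tip} at \code{divergence_age}
#' (time before present) and attaches \code{new_tip} there, so the pair
#' become sisters whose most recent common ancestor sits at exactly
#' \code{divergence_age}. Used to add taxa whose split dates are known from
#' calibration sources but that are absent from the base supertree (for
#' example a 3 Myr North Island / South Island robin divergence, or a
#' 0.015 Myr dog/wolf divergence). The tree stays ultrametric.
#'
#' @param tree a \code{phylo} object, ultrametric.
#' @param tip existing tip label.
#' @param new_tip label to add; must not already be present.
#' @param divergence_age split age in the tree's time units; must be strictly
#'   younger than the age of \code{tip}'s parent node.
#' @return a \code{phylo} object with one more tip.
#' @export
graft_split <- function(tree, tip, new_tip, divergence_age) {
  validate_tree(tree)
  if (!tip %in% tree$tip.label) stop("tip not in tree: ", tip, call. = FALSE)
  if (new_tip %in% tree$tip.label) stop("tip already present: ", new_tip, call. = FALSE)
  if (divergence_age <= 0) stop("divergence_age must be positive", call. = FALSE)
  i <- match(tip, tree$tip.label)
  parent_age <- tree$edge.length[tree$edge[, 2] == i]
  if (divergence_age >= parent_age) {
    stop(sprintf("divergence_age (%g) must be younger than the parent node age (%g)",
                 divergence_age, parent_age), call. = FALSE)
  }
  sister <- ape::read.tree(text = sprintf("(%s:%.12g);", new_tip, divergence_age))
  out <- ape::bind.tree(tree, sister, where = i, position = divergence_age)
  validate_tree(out)
}

#' Phylogenetic correlation matrix from an ultrametric tree
#'
#' Builds the species correlation matrix V whose (i, j) entry is the shared
#' root-to-MRCA path length of tips i and j divided by total tree depth
#' (unit diagonal). Under a Brownian-motion model of trait evolution this is
#' the expected correlation of species-level effects; tree depth divides
#' out, so V is a correlation rather than a covariance matrix.
#'
#' @param tree a \code{phylo} object.
#' @param labels ordered species labels; defaults to all tips. Every label
#'   must be a tip of the tree.
#' @return a \code{species_cov} object: list with \code{labels}, \code{V}
#'   (correlation matrix), and slots \code{M}, \code{lambda} filled by
#'   \code{\link{lambda_mix}}.
#' @export
tree_to_correlation <- function(tree, labels = NULL) {
  validate_tree(tree)
  if (is.null(labels)) labels <- tree$tip.label
  missing <- setdiff(labels, tree$tip.label)
  if (length(missing)) {
    stop("species not in tree: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  V <- suppressWarnings(ape::vcv.phylo(tree, corr = TRUE))[labels, labels, drop = FALSE]
  V <- (V + t(V)) / 2
  diag(V) <- 1
  structure(list(labels = labels, V = V, M = NULL, lambda = NULL),
            class = "species_cov")
}

#' @export
print.species_cov <- function(x, ...) {
  cat(sprintf("Phylogenetic correlation over %d species", length(x$labels)))
  if (!is.null(x$lambda)) cat(sprintf("; lambda-mixed at lambda = %.3g", x$lambda))
  cat("\n")
  invisible(x)
}

#' Pagel's lambda mixing of a phylogenetic correlation with the identity
#'
#' Computes M = lambda * V + (1 - lambda) * I. At lambda = 0 species effects
#' are independent; at lambda = 1 their correlation is fully determined by
#' the phylogeny. The diagonal stays exactly 1 and M remains positive
#' semidefinite for any lambda in [0, 1] (a convex combination of PSD
#' matrices).
#'
#' @param cov a \code{species_cov} object.
#' @param lam phylogenetic-signal parameter in [0, 1].
#' @return the \code{species_cov} with \code{M} and \code{lambda} filled in.
#' @export
lambda_mix <- function(cov, lam) {
  stopifnot(inherits(cov, "species_cov"))
  if (!is.numeric(lam) || length(lam) != 1L || is.na(lam) || lam < 0 || lam > 1) {
    stop("lambda must be a single value in [0, 1]", call. = FALSE)
  }
  M <- lam * cov$V + (1 - lam) * diag(nrow(cov$V))
  dimnames(M) <- dimnames(cov$V)
  cov$M <- M
  cov$lambda <- lam
  cov
}

#' Phylogenetic generalized least squares residuals
#'
#' Fits y = a + b x by GLS with residual correlation V (Brownian motion,
#' lambda fixed at 1) and returns the raw residuals y - y-hat. This is how
#' residual brain volume is computed: the residuals of log endocranial
#' volume regressed on log body mass under the phylogenetic correlation.
#' With V = I this reduces exactly to ordinary least squares.
#'
#' @param y,x numeric vectors aligned to \code{cov$labels}; no missing values.
#' @param cov a \code{species_cov} object.
#' @return named residual vector in the order of \code{cov$labels}.
#' @export
pgls_residuals <- function(y, x, cov) {
  stopifnot(inherits(cov, "species_cov"))
  n <- length(cov$labels)
  if (length(y) != n || length(x) != n) {
    stop("y and x must align with cov$labels", call. = FALSE)
  }
  if (anyNA(y) || anyNA(x)) stop("missing values not allowed in PGLS", call. = FALSE)
  X <- cbind(intercept = 1, x = x)
  L <- tryCatch(chol(cov$V), error = function(e)
    stop("phylogenetic correlation is not positive definite: ", conditionMessage(e),
         call. = FALSE))
  Xw <- backsolve(L, X, transpose = TRUE)
  yw <- backsolve(L, y, transpose = TRUE)
  qx <- qr(Xw)
  if (qx$rank < ncol(X)) stop("singular design in PGLS (x is constant?)", call. = FALSE)
  beta <- qr.coef(qx, yw)
  res <- as.vector(y - X %*% beta)
  names(res) <- cov$labels
  res
}
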