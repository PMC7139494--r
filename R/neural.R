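## Network-FA representation of structural connectivity.
##
## Connectivity is a symmetric 12x12 matrix of tract fractional
## anisotropy over six bilateral regions; a network is a named set of
## ROI pairs, and its Network FA is the collection of FA values of those
## tracts, modelled as logit-normal around a latent location delta.

#' ROI labels of the connectivity matrix
#'
#' Twelve regions: left/right thalamus, striatum, dorsolateral prefrontal
#' cortex (dlPFC), anterior cingulate cortex (ACC), inferior frontal
#' gyrus (IFG) and insula.
#'
#' @return character vector of 12 labels, left hemisphere first.
#' @export
roi_labels <- function() {
  regions <- c("Thalamus", "Striatum", "dlPFC", "ACC", "IFG", "Insula")
  c(paste0(regions, "_L"), paste0(regions, "_R"))
}

#' Construct a connectivity matrix
#'
#' Validates a square symmetric FA matrix over the 12 ROIs: zero
#' diagonal, off-diagonal entries in `[0, 1)` (0 marks a tract with no
#' reconstructed streamline).
#'
#' @param values 12x12 numeric matrix; dimnames must match
#'   [roi_labels()] (any order) or be absent, in which case the default
#'   order is assumed.
#' @return a `connectivity_matrix` (a matrix with ROI dimnames).
#' @export
connectivity_matrix <- function(values) {
  values <- as.matrix(values)
  labs <- roi_labels()
  if (!all(dim(values) == c(12L, 12L)))
    stop_invalid("connectivity matrix must be 12x12")
  if (is.null(rownames(values))) {
    dimnames(values) <- list(labs, labs)
  } else {
    if (!setequal(rownames(values), labs) || !identical(rownames(values), colnames(values)))
      stop_invalid("connectivity labels must match the 12 ROI labels")
    values <- values[labs, labs]
  }
  if (anyNA(values) || !is.numeric(values))
    stop_invalid("connectivity entries must be numeric and non-missing")
  if (any(diag(values) != 0))
    stop_invalid("connectivity diagonal must be zero")
  if (max(abs(values - t(values))) > 1e-9)
    stop_invalid("connectivity matrix must be symmetric")
  values <- (values + t(values)) / 2
  off <- values[upper.tri(values)]
  if (any(off < 0 | off >= 1))
    stop_invalid("FA values must lie in [0, 1)")
  structure(values, class = c("connectivity_matrix", "matrix", "array"))
}

#' @export
print.connectivity_matrix <- function(x, ...) {
  cat("12x12 FA connectivity matrix,",
      sum(x[upper.tri(x)] > 0), "reconstructed tracts\n")
  print(unclass(round(x, 3)))
  invisible(x)
}

#' Define a network as a set of ROI pairs
#'
#' @param name network label.
#' @param pairs two-column character matrix (or list of length-2 vectors)
#'   of unordered ROI-label pairs.
#' @return a `network_spec` object.
#' @export
network_spec <- function(name, pairs) {
  if (is.list(pairs)) pairs <- do.call(rbind, pairs)
  pairs <- as.matrix(pairs)
  if (ncol(pairs) != 2L) stop_invalid("`pairs` must have two columns")
  labs <- roi_labels()
  bad <- setdiff(c(pairs), labs)
  if (length(bad))
    stop_invalid(paste("unknown ROI labels:", paste(bad, collapse = ", ")))
  key <- apply(pairs, 1L, function(p) paste(sort(p), collapse = "|"))
  if (anyDuplicated(key)) stop_invalid("duplicated ROI pairs in network")
  if (any(pairs[, 1] == pairs[, 2])) stop_invalid("self-pairs are not tracts")
  structure(list(name = name, pairs = pairs), class = "network_spec")
}

#' @export
print.network_spec <- function(x, ...) {
  cat(sprintf("Network '%s' (%d tracts):\n", x$name, nrow(x$pairs)))
  apply(x$pairs, 1L, function(p) cat("  ", p[1], "--", p[2], "\n"))
  invisible(x)
}

#' The two confirmatory networks
#'
#' Network 1 connects ACC, insula and IFG (loss/risk-aversion
#' signalling); network 2 connects dlPFC, thalamus and striatum (the
#' cortico-striatal-thalamic path, top-down control).  Each consists of
#' the three within-triplet tracts in both hemispheres (6 tracts,
#' ipsilateral only).
#'
#' @return list of two [network_spec()] objects.
#' @export
default_networks <- function() {
  ipsi <- function(triplet) {
    base <- t(utils::combn(triplet, 2L))
    rbind(matrix(paste0(base, "_L"), ncol = 2L),
          matrix(paste0(base, "_R"), ncol = 2L))
  }
  list(
    network_spec("ACC-Insula-IFG", ipsi(c("ACC", "IFG", "Insula"))),
    network_spec("dlPFC-Thalamus-Striatum", ipsi(c("Striatum", "Thalamus", "dlPFC")))
  )
}

#' Extract a network's FA values from a connectivity matrix
#'
#' Reads one value per ROI pair (upper triangle; symmetry makes the
#' orientation irrelevant).  Entries equal to 0 denote tracts with no
#' reconstructed streamline; they are kept in the returned vector but
#' flagged with a warning and listed in the `missing` attribute, and the
#' likelihood code drops them.
#'
#' @param F a [connectivity_matrix()].
#' @param spec a [network_spec()].
#' @return named numeric vector, one entry per pair, in `spec` order.
#' @export
extract_network_fa <- function(F, spec) {
  stopifnot(inherits(F, "connectivity_matrix"), inherits(spec, "network_spec"))
  vals <- apply(spec$pairs, 1L, function(p) F[p[1], p[2]])
  names(vals) <- apply(spec$pairs, 1L, paste, collapse = "-")
  miss <- names(vals)[vals == 0]
  if (length(miss))
    warning(sprintf("network '%s': %d missing tract(s) (FA = 0): %s",
                    spec$name, length(miss), paste(miss, collapse = ", ")),
            call. = FALSE)
  structure(vals, missing = miss)
}

#' Logit-normal log-likelihood of network FA values
#'
#' Tract FA values are modelled on the logit scale as normal with
#' network location `delta` and inter-tract SD `sigma`:
#' `logit(f) ~ Normal(delta, sigma)`.
#'
#' @param fa_values FA values strictly in (0, 1) (missing tracts already
#'   removed); an empty vector gives 0.
#' @param delta latent network-FA location on the logit scale.
#' @param sigma inter-tract SD on the logit scale, `> 0`.
#' @return the log-likelihood.
#' @export
network_fa_loglik <- function(fa_values, delta, sigma) {
  check_finite(delta, "delta"); check_finite(sigma, "sigma")
  if (sigma <= 0) stop_invalid("`sigma` must be > 0")
  if (!length(fa_values)) return(0)
  check_finite(fa_values, "fa_values")
  if (any(fa_values <= 0 | fa_values >= 1))
    stop_invalid("FA values must lie strictly in (0, 1)")
  sum(dnorm(qlogis(fa_values), delta, sigma, log = TRUE))
}
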