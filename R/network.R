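#' Build the beta-Gaussian network stiffness matrix
#'
#' Constructs the elastic network for a monomer or a two-chain complex. The
#' model is a two-centroid description of each residue: the C-alpha atom
#' carries the backbone and a pseudo side-chain centroid (pseudo-Cbeta),
#' placed `cbeta_offset` Angstrom from the C-alpha along the normalized local
#' outward direction `w_i = 2 r_i - r_{i-1} - r_{i+1}`, carries side-chain
#' orientation. Glycines and chain-terminal residues carry no side-chain
#' centroid; so do residues whose three supporting C-alphas are collinear
#' (direction undefined, a warning is emitted).
#'
#' Every pair of centroids belonging to different residues and lying within
#' the cutoff `R_c` is coupled by a quadratic penalty on the component of the
#' relative displacement along the inter-centroid axis (the standard
#' distance-change penalty `[(u_i - u_j) . e_ij]^2`). Consecutive C-alphas of
#' the same chain are always coupled, with the backbone-strengthened
#' constant, so chain connectivity is retained even beyond the cutoff. The
#' pseudo-Cbeta displacement is not a free degree of freedom: it is the exact
#' linearization of the construction above, a fixed linear function of the
#' three supporting C-alpha displacements, and is substituted into every
#' coupling. The result is an effective `3N x 3N` stiffness matrix over
#' C-alpha displacements only, so predicted fluctuations refer to backbone
#' motion.
#'
#' The linearized pseudo-Cbeta map is
#' `d_beta_i = d_a_i + (l/|w|) (I - n n^T) (2 d_a_i - d_a_{i-1} - d_a_{i+1})`
#' with `n = w/|w|`; its blocks sum to the identity and it maps rigid-body
#' displacements of the C-alphas onto the corresponding rigid displacement of
#' the centroid, so the six rigid-body motions of a connected structure lie
#' exactly in the null space of the stiffness matrix.
#'
#' @param structure A `monomer_structure` or `dimer_structure`.
#' @param params [enm_params()].
#' @return An object of class `elastic_network`: list with `stiffness`
#'   (dense `3N x 3N` symmetric matrix, model units), `nodes` (tibble:
#'   `chain`, `resno`, `resid`, `idx`), `centroids` (tibble of interaction
#'   centers with owner residue and type), `couplings` (tibble: centroid pair,
#'   spring constant, kind), `G` (sparse coupling-row matrix such that
#'   `stiffness = t(G) %*% diag(kappa) %*% G`), and `params`.
#' @export
#' @examples
#' m <- make_monomer(20, geometry = "helix")
#' net <- build_network(m)
#' dim(net$stiffness)
build_network <- function(structure, params = enm_params()) {
  params <- as_enm_params(params)
  nodes <- network_nodes(structure)
  n <- nrow(nodes)
  if (n < 3) stop("need at least 3 residues to build a network",
                  call. = FALSE)
  coords <- as.matrix(nodes[, c("x", "y", "z")])
  if (!all(is.finite(coords)))
    stop("non-finite coordinates in input structure", call. = FALSE)

  cen <- place_centroids(nodes, coords, params)
  cpos <- cen$positions          # C x 3
  jac <- cen$jacobians           # list of 3 x (3*ns) matrices
  support <- cen$support         # list of residue-index vectors
  owner <- cen$owner
  ctype <- cen$type

  # contact enumeration over centroid pairs
  dmat <- as.matrix(stats::dist(cpos))
  within <- dmat <= params$cutoff
  diag(within) <- FALSE
  same_res <- outer(owner, owner, "==")
  within[same_res] <- FALSE
  pair_idx <- which(within & upper.tri(within), arr.ind = TRUE)

  # consecutive C-alpha pairs of the same chain: backbone springs, always on
  ca_of <- match(seq_len(n), which(ctype == "CA"))  # centroid idx of CA_i
  ca_cent <- which(ctype == "CA")
  bonded <- which(nodes$chain[-n] == nodes$chain[-1])  # i and i+1 same chain
  bb_pairs <- cbind(ca_cent[bonded], ca_cent[bonded + 1])

  is_bb <- rep(FALSE, nrow(pair_idx))
  if (nrow(pair_idx) > 0 && nrow(bb_pairs) > 0) {
    key <- paste(pmin(pair_idx[, 1], pair_idx[, 2]),
                 pmax(pair_idx[, 1], pair_idx[, 2]))
    bb_key <- paste(pmin(bb_pairs[, 1], bb_pairs[, 2]),
                    pmax(bb_pairs[, 1], bb_pairs[, 2]))
    is_bb <- key %in% bb_key
    miss <- !(bb_key %in% key)   # bonded pairs beyond cutoff still coupled
    if (any(miss)) {
      pair_idx <- rbind(pair_idx, bb_pairs[miss, , drop = FALSE])
      is_bb <- c(is_bb, rep(TRUE, sum(miss)))
    }
  } else if (nrow(bb_pairs) > 0 && nrow(pair_idx) == 0) {
    pair_idx <- bb_pairs
    is_bb <- rep(TRUE, nrow(bb_pairs))
  }

  kappa <- params$k * ifelse(is_bb, params$backbone_strengthening, 1)

  # one row of G per coupling: g = e^T (J_a - J_b) spread over supports
  np <- nrow(pair_idx)
  ii <- jj <- xx <- vector("list", np)
  for (p in seq_len(np)) {
    a <- pair_idx[p, 1]; b <- pair_idx[p, 2]
    e <- cpos[a, ] - cpos[b, ]
    en <- sqrt(sum(e^2))
    if (en < 1e-6)
      stop("coincident interaction centroids (residues ", owner[a],
           " and ", owner[b], "): degenerate geometry", call. = FALSE)
    e <- e / en
    cols_a <- as.vector(outer(c(-2L, -1L, 0L), 3L * support[[a]], "+"))
    cols_b <- as.vector(outer(c(-2L, -1L, 0L), 3L * support[[b]], "+"))
    va <- as.vector(e %*% jac[[a]])
    vb <- as.vector(e %*% jac[[b]])
    ii[[p]] <- rep.int(p, length(cols_a) + length(cols_b))
    jj[[p]] <- c(cols_a, cols_b)
    xx[[p]] <- c(va, -vb)
  }
  G <- Matrix::sparseMatrix(
    i = unlist(ii), j = unlist(jj), x = unlist(xx),
    dims = c(np, 3L * n)
  )
  M <- as.matrix(Matrix::crossprod(G, kappa * G))
  M <- (M + t(M)) / 2

  structure(
    list(
      stiffness = M,
      nodes = nodes,
      centroids = tibble::tibble(
        type = ctype, owner = owner,
        x = cpos[, 1], y = cpos[, 2], z = cpos[, 3]
      ),
      couplings = tibble::tibble(
        a = pair_idx[, 1], b = pair_idx[, 2], kappa = kappa,
        kind = ifelse(is_bb, "backbone", "nonbonded")
      ),
      G = G,
      params = params
    ),
    class = "elastic_network"
  )
}

#' @export
print.elastic_network <- function(x, ...) {
  cat("bGM elastic network:", nrow(x$nodes), "residues,",
      nrow(x$centroids), "centroids,", nrow(x$couplings), "couplings",
      paste0("(R_c = ", x$params$cutoff, " A)\n"))
  invisible(x)
}

# residue table of a monomer or dimer, first chain before second
network_nodes <- function(structure) {
  if (inherits(structure, "dimer_structure")) {
    res <- dplyr::bind_rows(
      tibble::as_tibble(structure$first),
      tibble::as_tibble(structure$second)
    )
  } else if (inherits(structure, "monomer_structure")) {
    res <- tibble::as_tibble(structure)
  } else {
    stop("structure must be a monomer_structure or dimer_structure",
         call. = FALSE)
  }
  res$idx <- seq_len(nrow(res))
  res
}

# place C-alpha and pseudo-Cbeta centroids; return positions, owners,
# support residue sets and slaving Jacobians (3 x 3*ns blocks)
place_centroids <- function(nodes, coords, params) {
  n <- nrow(nodes)
  l <- params$cbeta_offset
  I3 <- diag(3)

  type <- rep("CA", n)
  owner <- seq_len(n)
  support <- lapply(seq_len(n), identity)
  jac <- rep(list(I3), n)
  pos <- coords

  interior <- which(seq_len(n) > 1 & seq_len(n) < n &
                      nodes$chain == c(NA, nodes$chain[-n]) &
                      nodes$chain == c(nodes$chain[-1], NA) &
                      nodes$resid != "GLY")
  if (l > 0 && length(interior) > 0) {
    skipped <- 0L
    for (i in interior) {
      w <- 2 * coords[i, ] - coords[i - 1, ] - coords[i + 1, ]
      wn <- sqrt(sum(w^2))
      if (wn < 1e-6) { skipped <- skipped + 1L; next }
      nv <- w / wn
      P <- I3 - tcrossprod(nv)
      # d_beta = d_i + (l/|w|) P (2 d_i - d_{i-1} - d_{i+1})
      Bm <- -(l / wn) * P
      Bi <- I3 + (2 * l / wn) * P
      type <- c(type, "CB")
      owner <- c(owner, i)
      support <- c(support, list(c(i - 1L, i, i + 1L)))
      jac <- c(jac, list(cbind(Bm, Bi, Bm)))
      pos <- rbind(pos, coords[i, ] + l * nv)
    }
    if (skipped > 0)
      warning(skipped, " residue(s) with collinear local geometry: ",
              "side-chain centroid omitted", call. = FALSE)
  }
  list(positions = pos, type = type, owner = owner,
       support = support, jacobians = jac)
}
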