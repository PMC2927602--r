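#' Partition a complex network into monomer blocks
#'
#' Splits the stiffness matrix of a two-chain complex into the monomer
#' blocks `M_A`, `M_B` and the coupling block `G` of the block form
#' `[[M_A, G], [G^T, M_B]]`, with A the designated first chain (the chain
#' that defines the subunit reference frame).
#'
#' @param network An `elastic_network` built on a `dimer_structure`.
#' @param first_chain_id Chain id of monomer A; defaults to the first chain
#'   in the network's node table.
#' @return An object of class `block_partition`: `M_A`, `M_B`, `G`,
#'   `nodes_A`, `nodes_B`, `first_chain_id`.
#' @export
partition_network <- function(network, first_chain_id = NULL) {
  stopifnot(inherits(network, "elastic_network"))
  nodes <- network$nodes
  chains <- unique(nodes$chain)
  if (length(chains) != 2)
    stop("partitioning needs a two-chain network, found chains: ",
         paste(chains, collapse = ", "), call. = FALSE)
  if (is.null(first_chain_id)) first_chain_id <- chains[1]
  if (!first_chain_id %in% chains)
    stop("unknown chain id '", first_chain_id, "'", call. = FALSE)
  in_A <- nodes$chain == first_chain_id
  dof <- function(mask) as.vector(outer(c(-2L, -1L, 0L),
                                        3L * which(mask), "+"))
  iA <- dof(in_A); iB <- dof(!in_A)
  M <- network$stiffness
  structure(
    list(
      M_A = M[iA, iA, drop = FALSE],
      M_B = M[iB, iB, drop = FALSE],
      G = M[iA, iB, drop = FALSE],
      nodes_A = nodes[in_A, ],
      nodes_B = nodes[!in_A, ],
      first_chain_id = first_chain_id
    ),
    class = "block_partition"
  )
}

#' @export
print.block_partition <- function(x, ...) {
  cat("Block partition: A =", x$first_chain_id,
      paste0("(", nrow(x$nodes_A), " residues), B (",
             nrow(x$nodes_B), " residues), |G| = "),
      signif(norm(x$G, "F"), 4), "\n")
  invisible(x)
}

#' Integrate out the partner monomer
#'
#' Canonically integrating the Gaussian degrees of freedom of monomer B from
#' the complex free energy leaves a quadratic effective free energy for
#' monomer A with stiffness the Schur complement
#' `M_A_eff = M_A - G M_B^{-1} G^T`. `M_B` is positive definite exactly when
#' chain B is internally connected and in contact with A; if the chains are
#' not coupled, B keeps free rigid motions, `M_B` is singular, and the
#' marginalization is refused as physically undefined.
#'
#' @param partition A `block_partition`.
#' @param tol Relative smallest-eigenvalue tolerance for declaring `M_B`
#'   singular.
#' @return An object of class `effective_network`: `stiffness` (`M_A_eff`),
#'   `nodes` (residues of A), `first_chain_id`, `params` placeholder fields
#'   mirrored from the partition.
#' @export
marginalize_partner <- function(partition, tol = 1e-9) {
  stopifnot(inherits(partition, "block_partition"))
  M_B <- partition$M_B
  eB <- eigen((M_B + t(M_B)) / 2, symmetric = TRUE, only.values = TRUE)$values
  if (min(eB) <= tol * max(eB))
    stop("partner not coupled - marginalization undefined ",
         "(M_B numerically singular)", call. = FALSE)
  S <- partition$M_A - partition$G %*% solve(M_B, t(partition$G))
  S <- (S + t(S)) / 2
  structure(
    list(stiffness = S, nodes = partition$nodes_A,
         first_chain_id = partition$first_chain_id),
    class = "effective_network"
  )
}

#' @export
print.effective_network <- function(x, ...) {
  cat("Effective network for chain", x$first_chain_id, "-",
      nrow(x$nodes), "residues (partner integrated out)\n")
  invisible(x)
}

#' Bound and unbound mobility of the first monomer
#'
#' Computes, residue by residue for the first chain of a dimer, the RMSF in
#' the bound form (partner monomer present, its degrees of freedom
#' integrated out analytically) and in the unbound form (the
#' structurally-quenched monomer obtained by in-silico splitting, network
#' rebuilt from its coordinates alone). In the default subunit frame, rigid
#' rotations and translations are removed with respect to the C-alpha trace
#' of the first chain only: the six-dimensional null space of the effective
#' stiffness matrix is exactly that subunit frame. With `frame = "complex"`
#' the bound profile instead removes rigid motions of the whole complex
#' (standard whole-system convention) and is read off the complex
#' eigensystem.
#'
#' Because the partner can only constrain monomer A, the bound RMSF is less
#' than or equal to the unbound RMSF for every residue.
#'
#' @param dimer A `dimer_structure` (must pass [validate_for_enm()]).
#' @param params [enm_params()].
#' @param frame `"subunit"` (default) or `"complex"`.
#' @param validate Set `FALSE` to skip the zero-mode pre-check (it is then
#'   still enforced mode-by-mode downstream).
#' @return A tibble (`paired_profile`): `chain`, `resno`, `resid`,
#'   `rmsf_bound`, `rmsf_unbound`, `frame`, one row per residue of the first
#'   chain.
#' @export
#' @examples
#' d <- make_dimer(synthetic_dimer_spec(n_first = 16, n_second = 16,
#'                                      target_interchain_contacts = 8))
#' bound_unbound_profiles(d)
bound_unbound_profiles <- function(dimer, params = enm_params(),
                                   frame = c("subunit", "complex"),
                                   validate = TRUE) {
  stopifnot(inherits(dimer, "dimer_structure"))
  params <- as_enm_params(params)
  frame <- match.arg(frame)
  if (validate) {
    rep <- validate_for_enm(dimer, params)
    if (!rep$enm_suitable)
      stop("extra zero modes - structure unsuitable (complex: ",
           rep$n_zero_modes_complex, ", first: ", rep$n_zero_modes_first,
           ", second: ", rep$n_zero_modes_second, ")", call. = FALSE)
  }
  cx <- build_network(dimer, params)
  first_id <- attr(dimer$first, "chain_id")

  if (frame == "subunit") {
    part <- partition_network(cx, first_id)
    eff <- marginalize_partner(part)
    sp <- mode_spectrum(eff$stiffness, params)
    bound <- rmsf_profile(sp, nodes = part$nodes_A, frame = "subunit")
  } else {
    sp <- mode_spectrum(cx)
    all_prof <- rmsf_profile(sp, frame = "complex")
    bound <- all_prof[cx$nodes$chain == first_id, ]
  }

  un_net <- build_network(dimer$first, params)
  un_sp <- mode_spectrum(un_net)
  unbound <- rmsf_profile(un_sp, nodes = un_net$nodes, frame = frame)

  out <- tibble::tibble(
    chain = unbound$chain,
    resno = unbound$resno,
    resid = unbound$resid,
    rmsf_bound = bound$rmsf,
    rmsf_unbound = unbound$rmsf,
    frame = frame
  )
  class(out) <- c("paired_profile", class(out))
  out
}
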