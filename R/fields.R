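#' Extracellular species tracked on the tissue lattice
#'
#' Morphogens (Wnt, free BMP, SFRP1, Hedgehog) and inflammatory mediators
#' (TLR4 ligand/DAMPs, TNF-alpha, IFN-gamma, interleukins). Concentrations
#' are in arbitrary units; all thresholds in the model are expressed relative
#' to source strengths in the configuration.
#' @export
CV_SPECIES <- c("WNT", "BMP_FREE", "SFRP1", "HH", "TLR4_LIGAND",
                "TNFA", "IFNG", "IL6", "IL10", "IL13", "IL15")

#' Create a morphogen/cytokine field
#'
#' A field is a per-patch non-negative concentration vector over a topology,
#' with a diffusion rate, a first-order decay rate and point sources.
#'
#' @param topology A `cv_topology`.
#' @param species Species name (one of [CV_SPECIES]).
#' @param D Diffusion rate, patch^2 per minute (explicit 4-neighbor lattice
#'   diffusion with closed boundaries at crypt base and villus tip and
#'   circumferential wrap).
#' @param k_decay First-order decay rate per minute.
#' @param conc Optional initial concentration (scalar or length `n_patches`).
#' @param sources Named numeric vector: emission per minute keyed by patch id
#'   (as character), or NULL.
#' @return A `cv_field` list.
#' @export
new_field <- function(topology, species, D = 0, k_decay = 0, conc = 0,
                      sources = NULL) {
  stopifnot(inherits(topology, "cv_topology"))
  species <- match.arg(species, CV_SPECIES)
  if (D < 0 || k_decay < 0 || k_decay > 1)
    stop("D must be >= 0 and k_decay in [0, 1]", call. = FALSE)
  conc <- rep_len(as.numeric(conc), topology$n_patches)
  if (any(conc < 0)) stop("concentrations must be non-negative", call. = FALSE)
  f <- list(species = species, conc = conc, D = D, k_decay = k_decay,
            sources = sources, n = topology$n_patches)
  class(f) <- "cv_field"
  f
}

# graph Laplacian of the patch lattice (sparse), used by the explicit scheme
lattice_laplacian <- function(topology) {
  adj <- topology$adj
  n <- topology$n_patches
  from <- rep(seq_len(n), 4L)
  to <- as.integer(adj)
  keep <- !is.na(to)
  from <- from[keep]; to <- to[keep]
  deg <- tabulate(from, nbins = n)
  Matrix::sparseMatrix(i = c(from, seq_len(n)), j = c(to, seq_len(n)),
                       x = c(rep(1, length(from)), -deg), dims = c(n, n))
}

#' Precompute a one-tick diffusion/decay operator
#'
#' Builds the sparse matrix `A` such that `conc_new = A %*% conc_old`
#' advances a field by `dt` minutes: `m` explicit diffusion substeps
#' interleaved with per-substep exponential-equivalent decay. The substep is
#' chosen so that `4 * D * dt_sub <= 0.8`, which keeps all operator entries
#' non-negative (no concentration can go negative) and, with zero decay,
#' makes every row sum to 1 (exact mass conservation under the closed
#' boundaries).
#'
#' @param topology A `cv_topology`.
#' @param D Diffusion rate, patch^2/min.
#' @param k_decay Decay rate per minute.
#' @param dt Tick length in minutes.
#' @param dt_sub Optional explicit substep (minutes). If supplied it must
#'   satisfy the stability bound `4 * D * dt_sub <= 1`; violating it is a
#'   configuration error, not a silent negative-concentration update.
#' @return A sparse `dgCMatrix`.
#' @export
make_field_operator <- function(topology, D, k_decay, dt, dt_sub = NULL) {
  L <- lattice_laplacian(topology)
  n <- topology$n_patches
  if (is.null(dt_sub)) {
    m <- if (D > 0) max(1L, ceiling(4 * D * dt / 0.8)) else 1L
    dt_sub <- dt / m
  } else {
    if (4 * D * dt_sub > 1)
      stop("unstable diffusion substep: need 4 * D * dt_sub <= 1 (got ",
           signif(4 * D * dt_sub, 3), ")", call. = FALSE)
    m <- as.integer(round(dt / dt_sub))
    if (m < 1L || abs(m * dt_sub - dt) > 1e-9)
      stop("dt_sub must divide dt", call. = FALSE)
  }
  step1 <- Matrix::Diagonal(n) * exp(-k_decay * dt_sub) +
    (D * dt_sub * exp(-k_decay * dt_sub)) * L
  A <- Matrix::Diagonal(n)
  P <- step1
  mm <- m
  while (mm > 0) {            # fast exponentiation
    if (mm %% 2L == 1L) A <- trim_operator(A %*% P)
    mm <- mm %/% 2L
    if (mm > 0) P <- trim_operator(P %*% P)
  }
  methods::as(A, "CsparseMatrix")
}

# drop negligible kernel entries (far tails of the substepped explicit
# kernel) and renormalize rows so row mass — hence conservation — is kept
trim_operator <- function(A, tol = 1e-6) {
  rs0 <- Matrix::rowSums(A)
  A <- Matrix::drop0(A, tol = tol)
  rs1 <- Matrix::rowSums(A)
  scale <- ifelse(rs1 > 0, rs0 / rs1, 1)
  Matrix::Diagonal(x = scale) %*% A
}

#' Advance a field one tick
#'
#' Deposits sources, then applies lattice diffusion and first-order decay for
#' `dt` minutes. Non-negativity is preserved by construction.
#'
#' @param field A `cv_field`.
#' @param topology The matching `cv_topology`.
#' @param dt Minutes to advance.
#' @param dt_sub Optional explicit substep; see [make_field_operator()].
#' @return The updated `cv_field`.
#' @export
step_field <- function(field, topology, dt, dt_sub = NULL) {
  stopifnot(inherits(field, "cv_field"), inherits(topology, "cv_topology"))
  key <- paste(field$D, field$k_decay, dt, dt_sub %||% "auto")
  if (is.null(field$.op) || !identical(field$.op_key, key)) {
    field$.op <- make_field_operator(topology, field$D, field$k_decay, dt, dt_sub)
    field$.op_key <- key
  }
  conc <- field$conc
  if (!is.null(field$sources) && length(field$sources)) {
    ids <- as.integer(names(field$sources))
    conc[ids] <- conc[ids] + as.numeric(field$sources) * dt
  }
  field$conc <- as.numeric(field$.op %*% conc)
  field
}

#' Read a field at one patch
#'
#' @param field A `cv_field`.
#' @param patch_id Patch id.
#' @return The concentration (read-only access).
#' @export
sample_field <- function(field, patch_id) {
  if (length(patch_id) != 1L || is.na(patch_id) ||
      patch_id < 1L || patch_id > field$n)
    stop("unknown patch_id: ", patch_id, call. = FALSE)
  field$conc[patch_id]
}

#' Deposit mass into a field
#'
#' @param field A `cv_field`.
#' @param patch_id Patch id(s).
#' @param amount Amount(s) to add (recycled).
#' @return The updated field.
#' @export
deposit <- function(field, patch_id, amount) {
  if (any(patch_id < 1L | patch_id > field$n))
    stop("unknown patch_id", call. = FALSE)
  field$conc[patch_id] <- field$conc[patch_id] + amount
  field
}

#' Check the homeostatic Wnt profile
#'
#' TRUE iff the circumferential-mean Wnt profile peaks in the bottom quarter
#' of the crypt and Wnt is below `eps` on every patch above the crypt-villus
#' junction — the pattern of a source at the crypt base opposed by
#' villus-derived SFRP1.
#'
#' @param field A `cv_field` (normally WNT).
#' @param topology The matching `cv_topology`.
#' @param junction_axial_um Axial position of the crypt-villus junction in
#'   micrometres (from [measure_architecture()]).
#' @param eps Activity threshold; defaults to the package's Wnt-loss
#'   threshold.
#' @return Logical scalar.
#' @export
wnt_profile_check <- function(field, topology, junction_axial_um,
                              eps = cv_defaults$signaling$wnt_eps) {
  prof <- gradient_profile(field, topology)
  if (max(prof$mean_level) < eps) return(FALSE)  # no Wnt activity anywhere
  peak <- prof$axial_pos[which.max(prof$mean_level)]
  crypt_extent <- topology$config$crypt_rows * topology$config$patch_um
  above <- topology$patches$axial_pos > junction_axial_um
  peak <= 0.25 * crypt_extent && all(field$conc[above] < eps)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
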