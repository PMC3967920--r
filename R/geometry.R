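#' Geometry configuration for a crypt-villus tissue lattice
#'
#' Describes a fixed matrix of rectangular prisms (crypts and villi), each
#' unwrapped onto a 2-D grid of square patches. One patch holds at most one
#' live epithelial cell (patch size = one cell diameter). Grids are sized to a
#' maximal extent; the realized crypt depth and villus height are emergent
#' from where proliferative vs differentiated cells sit, so defaults leave
#' head-room above the homeostatic extents for hyperplasia.
#'
#' @param n_villi Number of villi (>= 1).
#' @param crypts_per_villus Number of crypts feeding each villus (>= 1).
#' @param crypt_width Patches around a crypt circumference.
#' @param crypt_rows Rows of the unwrapped crypt grid (base -> rim).
#' @param villus_rows Rows of the unwrapped villus grid (base -> tip).
#' @param patch_um Physical patch edge length in micrometres.
#' @return A list of class `cv_geometry`.
#' @export
tissue_config <- function(n_villi = 1L, crypts_per_villus = 1L,
                          crypt_width = 16L, crypt_rows = 18L,
                          villus_rows = 75L, patch_um = 20) {
  g <- list(n_villi = as.integer(n_villi),
            crypts_per_villus = as.integer(crypts_per_villus),
            crypt_width = as.integer(crypt_width),
            crypt_rows = as.integer(crypt_rows),
            villus_rows = as.integer(villus_rows),
            patch_um = as.numeric(patch_um))
  class(g) <- "cv_geometry"
  validate_geometry(g)
  g
}

validate_geometry <- function(g) {
  stopifnot(is.list(g))
  num_ok <- function(x) length(x) == 1 && is.finite(x)
  for (f in c("n_villi", "crypts_per_villus", "crypt_width", "crypt_rows",
              "villus_rows", "patch_um")) {
    if (!num_ok(g[[f]]) || g[[f]] <= 0)
      stop("geometry field '", f, "' must be a single positive number", call. = FALSE)
  }
  if (g$n_villi < 1L) stop("need at least one villus", call. = FALSE)
  if (g$crypts_per_villus < 1L)
    stop("every crypt must link to a villus: crypts_per_villus >= 1", call. = FALSE)
  invisible(g)
}

#' Build the fixed crypt-villus tissue topology
#'
#' Constructs the patch lattice for a matrix of crypt and villus prisms, each
#' unwrapped to a 2-D grid with circumferential wrap-around, together with the
#' patch adjacency table, the bijective rim-to-base links joining each crypt
#' to its villus, and abstracted blood-vessel arrival sites (one per crypt, at
#' mid-crypt depth) where circulating inflammatory cells enter the tissue.
#' The construction is deterministic: no random numbers are consumed.
#'
#' The villus circumference equals `crypts_per_villus * crypt_width`, so the
#' rim row of each crypt maps one-to-one onto a contiguous arc of the villus
#' base row: cells migrating off a crypt continue onto its villus.
#'
#' @param config A `cv_geometry` from [tissue_config()] (or a plain list with
#'   the same fields).
#' @return A `cv_topology` list: `patches` (tibble: patch_id, unit_id, kind,
#'   row, circ_index, axial_pos, is_vessel_adjacent), `units` (tibble),
#'   `links` (tibble crypt_patch/villus_patch), `vessel_sites` (patch ids),
#'   `adj` (n x 4 integer matrix: up, down, left, right; NA where absent),
#'   `n_patches`, `L_total_um`, and the originating `config`.
#' @examples
#' topo <- build_tissue(tissue_config(crypt_rows = 12, villus_rows = 50))
#' topo$n_patches  # 16*12 + 16*50 = 992
#' @export
build_tissue <- function(config = tissue_config()) {
  if (!inherits(config, "cv_geometry")) {
    config <- do.call(tissue_config, config[c("n_villi", "crypts_per_villus",
                                              "crypt_width", "crypt_rows",
                                              "villus_rows", "patch_um")])
  }
  validate_geometry(config)
  g <- config
  vw <- g$crypt_width * g$crypts_per_villus  # villus circumference in patches

  units <- list(); patches <- list(); links <- list()
  uid <- 0L; pid0 <- 0L
  unit_offset <- integer(0)

  for (v in seq_len(g$n_villi)) {
    crypt_uids <- integer(g$crypts_per_villus)
    for (cc in seq_len(g$crypts_per_villus)) {
      uid <- uid + 1L
      crypt_uids[cc] <- uid
      units[[uid]] <- data.frame(unit_id = uid, kind = "crypt", complex = v,
                                 width = g$crypt_width, height = g$crypt_rows,
                                 patch_um = g$patch_um)
      unit_offset[uid] <- pid0
      pid0 <- pid0 + g$crypt_width * g$crypt_rows
    }
    uid <- uid + 1L
    vuid <- uid
    units[[uid]] <- data.frame(unit_id = uid, kind = "villus", complex = v,
                               width = vw, height = g$villus_rows,
                               patch_um = g$patch_um)
    unit_offset[uid] <- pid0
    pid0 <- pid0 + vw * g$villus_rows

    # rim -> base links: crypt cc, circ j  ->  villus circ (cc-1)*crypt_width + j
    for (cc in seq_len(g$crypts_per_villus)) {
      cu <- crypt_uids[cc]
      j <- seq_len(g$crypt_width) - 1L
      crypt_patch <- unit_offset[cu] + j * g$crypt_rows + g$crypt_rows
      villus_patch <- unit_offset[vuid] + ((cc - 1L) * g$crypt_width + j) * g$villus_rows + 1L
      links[[length(links) + 1L]] <- data.frame(crypt_patch = crypt_patch,
                                                villus_patch = villus_patch)
    }
  }
  units <- do.call(rbind, units)
  links <- do.call(rbind, links)
  n <- pid0

  # per-patch table (column-major within unit: circ index outer, row inner)
  pu <- rep.int(units$unit_id, units$width * units$height)
  kind <- rep.int(units$kind, units$width * units$height)
  row <- unlist(lapply(seq_len(nrow(units)), function(i)
    rep(seq_len(units$height[i]), times = units$width[i])), use.names = FALSE)
  circ <- unlist(lapply(seq_len(nrow(units)), function(i)
    rep(seq_len(units$width[i]) - 1L, each = units$height[i])), use.names = FALSE)
  axial <- ifelse(kind == "crypt",
                  (row - 0.5) * g$patch_um,
                  (g$crypt_rows + row - 0.5) * g$patch_um)

  # vessel sites: one per crypt at mid-crypt depth, circ 0
  mid <- max(1L, as.integer(ceiling(g$crypt_rows / 2)))
  cr <- units[units$kind == "crypt", ]
  vessel_sites <- unit_offset[cr$unit_id] + mid
  is_vessel <- seq_len(n) %in% vessel_sites

  # adjacency: up (towards tip), down (towards base), left, right
  adj <- matrix(NA_integer_, nrow = n, ncol = 4,
                dimnames = list(NULL, c("up", "down", "left", "right")))
  for (i in seq_len(nrow(units))) {
    w <- units$width[i]; h <- units$height[i]; off <- unit_offset[units$unit_id[i]]
    ids <- matrix(off + seq_len(w * h), nrow = h, ncol = w)  # [row, circ+1]
    up <- rbind(ids[-1, , drop = FALSE], NA_integer_)
    dn <- rbind(NA_integer_, ids[-h, , drop = FALSE])
    lf <- ids[, c(w, seq_len(w - 1L)), drop = FALSE]
    rt <- ids[, c(seq.int(2L, length.out = w - 1L), 1L), drop = FALSE]
    if (w == 1L) { lf[] <- NA_integer_; rt[] <- NA_integer_ }
    adj[as.vector(ids), ] <- cbind(as.vector(up), as.vector(dn),
                                   as.vector(lf), as.vector(rt))
  }
  # stitch rim -> base
  adj[links$crypt_patch, "up"] <- links$villus_patch
  adj[links$villus_patch, "down"] <- links$crypt_patch

  topo <- list(
    patches = tibble::tibble(patch_id = seq_len(n), unit_id = pu, kind = kind,
                             row = row, circ_index = circ, axial_pos = axial,
                             is_vessel_adjacent = is_vessel),
    units = tibble::as_tibble(units),
    links = tibble::as_tibble(links),
    vessel_sites = as.integer(vessel_sites),
    adj = adj,
    n_patches = n,
    L_total_um = (g$crypt_rows + g$villus_rows) * g$patch_um,
    config = g)
  class(topo) <- "cv_topology"
  topo
}

#' Lattice neighbors of a patch
#'
#' Returns the ids of the 3 or 4 lattice neighbors of a patch: up/down along
#' the crypt-base-to-villus-tip axis (crossing the rim-base link between a
#' crypt and its villus) and left/right around the circumference with
#' wrap-around. The villus tip row has no up neighbor; the crypt base row has
#' no down neighbor. Adjacency is symmetric.
#'
#' @param topology A `cv_topology`.
#' @param patch_id A single patch id.
#' @return Integer vector of neighbor patch ids (length 3 or 4).
#' @export
neighbors <- function(topology, patch_id) {
  stopifnot(inherits(topology, "cv_topology"))
  if (length(patch_id) != 1L || is.na(patch_id) ||
      patch_id < 1L || patch_id > topology$n_patches)
    stop("unknown patch_id: ", patch_id, call. = FALSE)
  nb <- topology$adj[patch_id, ]
  as.integer(nb[!is.na(nb)])
}

#' Tabular topology dump
#'
#' One row per patch: patch_id, unit_id, kind, axial position (um) and
#' circumferential index, suitable for writing as TSV.
#'
#' @param topology A `cv_topology`.
#' @return A tibble.
#' @export
topology_table <- function(topology) {
  stopifnot(inherits(topology, "cv_topology"))
  topology$patches[, c("patch_id", "unit_id", "kind", "axial_pos", "circ_index")]
}

#' @export
print.cv_topology <- function(x, ...) {
  g <- x$config
  cat("<cv_topology> ", g$n_villi, " villus/villi, ",
      g$crypts_per_villus, " crypt(s) each\n",
      "  crypt grid ", g$crypt_width, "x", g$crypt_rows,
      ", villus grid ", g$crypt_width * g$crypts_per_villus, "x", g$villus_rows,
      ", patch ", g$patch_um, " um\n",
      "  ", x$n_patches, " patches, axial extent ", x$L_total_um, " um\n", sep = "")
  invisible(x)
}
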