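#' Specification of the parameterised voxel mouse phantom
#'
#' The phantom is a simplified digital mouse built from geometric primitives
#' (a prolate-ellipsoid body, spherical/ellipsoidal organs, a dorsal
#' skeleton cylinder containing a coaxial red-marrow core, a spherical
#' submandibular gland, and a flank tumour modelled as a solid ellipsoid
#' with axis ratio 1:2:2 whose short axis is perpendicular to the skin,
#' attached outside the body contour on the right flank). Organ linear
#' dimensions are solved from the requested masses at the given tissue
#' density, so the phantom reproduces the organ sizes of a kinetic study.
#'
#' @param body_weight_g total body weight in grams (includes all organs and
#'   the tumour-free remainder tissue; the tumour is added on top).
#' @param organ_masses_g named numeric vector of organ masses in grams.
#'   Defaults are literature-informed values for a ~25 g adult mouse.
#' @param tumor_mass_g tumour mass in grams.
#' @param grid integer triple (nx, ny, nz) of voxel counts.
#' @param voxel_size_mm cubic voxel edge in mm.
#' @param density_g_cm3 tissue density; all regions are water-equivalent by
#'   default.
#' @return object of class `phantom_spec`.
#' @export
phantom_spec <- function(body_weight_g = 25,
                         organ_masses_g = c(
                           brain = 0.40, submandibular = 0.10, lung = 0.15,
                           heart = 0.15, liver = 1.30, spleen = 0.10,
                           kidney = 0.40, gi = 2.00, testes = 0.20,
                           bone = 1.80, marrow = 0.20),
                         tumor_mass_g = 0.5,
                         grid = c(160L, 160L, 440L),
                         voxel_size_mm = 0.25,
                         density_g_cm3 = 1.0) {
  stopifnot(body_weight_g > 0, tumor_mass_g > 0,
            length(grid) == 3, all(grid > 0),
            voxel_size_mm > 0, density_g_cm3 > 0)
  if (is.null(names(organ_masses_g)) || any(!nzchar(names(organ_masses_g))))
    stop("organ_masses_g must be a named vector")
  if (any(organ_masses_g <= 0)) stop("organ masses must be positive")
  if (sum(organ_masses_g) >= body_weight_g)
    stop("organ masses exceed body weight: no remainder tissue left")
  structure(list(body_weight_g = body_weight_g,
                 organ_masses_g = organ_masses_g,
                 tumor_mass_g = tumor_mass_g,
                 grid = as.integer(grid),
                 voxel_size_mm = voxel_size_mm,
                 density_g_cm3 = density_g_cm3),
            class = "phantom_spec")
}

# anatomical layout: positions as fractions of the body semi-axes
# (x right, y ventral->dorsal with dorsal positive, z tail->head), axis
# ratios of the ellipsoidal primitives; spheres are ratio (1,1,1)
.phantom_layout <- function() {
  list(
    brain         = list(shape = "ellipsoid", ratio = c(1, 1, 1),        pos = c(0.00, 0.00, 0.80)),
    submandibular = list(shape = "ellipsoid", ratio = c(1, 1, 1),        pos = c(0.00, -0.42, 0.60)),
    lung          = list(shape = "ellipsoid", ratio = c(1.3, 1.0, 0.9),  pos = c(0.18, 0.10, 0.42)),
    heart         = list(shape = "ellipsoid", ratio = c(1, 1, 1),        pos = c(-0.12, -0.25, 0.30)),
    liver         = list(shape = "ellipsoid", ratio = c(1.8, 1.3, 0.75), pos = c(0.00, -0.16, 0.10)),
    kidney        = list(shape = "pair",      ratio = c(1, 1, 1),        pos = c(0.32, 0.05, -0.08)),
    spleen        = list(shape = "ellipsoid", ratio = c(1, 1, 1),        pos = c(-0.50, -0.18, -0.26)),
    gi            = list(shape = "ellipsoid", ratio = c(1.5, 1.1, 0.85), pos = c(0.05, -0.20, -0.45)),
    testes        = list(shape = "ellipsoid", ratio = c(1, 1, 1),        pos = c(0.00, -0.10, -0.75))
  )
}

# voxelise one axis-aligned ellipsoid into `labels`, claiming only voxels
# where `claimable` is TRUE; returns updated labels and the voxel count
.vox_ellipsoid <- function(labels, claimable, dims, vs, center, semi, id) {
  xi <- ((seq_len(dims[1]) - 0.5) * vs - center[1]) / semi[1]
  yi <- ((seq_len(dims[2]) - 0.5) * vs - center[2]) / semi[2]
  zi <- ((seq_len(dims[3]) - 0.5) * vs - center[3]) / semi[3]
  ix <- which(abs(xi) <= 1); iy <- which(abs(yi) <= 1); iz <- which(abs(zi) <= 1)
  n <- 0L
  if (length(ix) && length(iy) && length(iz)) {
    A <- outer(xi[ix]^2, yi[iy]^2, "+")
    for (k in iz) {
      m <- A <= 1 - zi[k]^2
      sub <- labels[ix, iy, k]
      dim(sub) <- dim(m)
      cl <- claimable[ix, iy, k]
      dim(cl) <- dim(m)
      take <- m & cl
      sub[take] <- id
      labels[ix, iy, k] <- sub
      n <- n + sum(take)
    }
  }
  list(labels = labels, count = n)
}

# z-aligned annular cylinder (r_in = 0 gives a full cylinder)
.vox_cylinder <- function(labels, claimable, dims, vs, center_xy, r_out, r_in,
                          z_range, id) {
  xi <- (seq_len(dims[1]) - 0.5) * vs - center_xy[1]
  yi <- (seq_len(dims[2]) - 0.5) * vs - center_xy[2]
  zc <- (seq_len(dims[3]) - 0.5) * vs
  iz <- which(zc >= z_range[1] & zc <= z_range[2])
  R2 <- outer(xi^2, yi^2, "+")
  m <- R2 <= r_out^2 & R2 > r_in^2
  n <- 0L
  for (k in iz) {
    sub <- labels[, , k]
    take <- m & claimable[, , k]
    sub[take] <- id
    labels[, , k] <- sub
    n <- n + sum(take)
  }
  list(labels = labels, count = n)
}

#' Build the voxel phantom
#'
#' Deterministically voxelises the phantom described by a [phantom_spec()].
#' Each organ's linear scale is calibrated by a short secant iteration so
#' that the achieved voxel mass matches the target within tolerance
#' (quantisation permitting); an organ too small to occupy a voxel at the
#' given resolution raises an error suggesting a finer voxel size.
#'
#' @param spec a [phantom_spec()].
#' @param mass_tol relative tolerance on achieved region masses.
#' @return object of class `voxel_phantom`: `labels` (integer 3-D array,
#'   0 = outside the animal), `region_table` (id, region, target and
#'   achieved mass), `voxel_size_mm`, `density_g_cm3`, `provenance` (the
#'   spec). Voxel indices are 0-based in the export convention, z along the
#'   body axis, the right flank (tumour side) at +x.
#' @export
build_phantom <- function(spec, mass_tol = 0.05) {
  stopifnot(inherits(spec, "phantom_spec"))
  dims <- spec$grid; vs <- spec$voxel_size_mm
  rho_mm <- spec$density_g_cm3 / 1000  # g per mm^3
  vox_mass <- vs^3 * rho_mm

  mm3 <- function(mass_g) mass_g / rho_mm
  if (min(mm3(c(spec$organ_masses_g, spec$tumor_mass_g))) < vs^3)
    stop(sprintf(
      "resolution error: smallest region needs < 1 voxel; use voxel_size_mm <= %.3g",
      min(mm3(c(spec$organ_masses_g, spec$tumor_mass_g)))^(1/3)))

  # body: prolate ellipsoid with polar/equatorial ratio 3.2, volume = weight
  Vbody <- mm3(spec$body_weight_g)
  rb <- (Vbody * 3 / (4 * pi * 3.2))^(1/3)
  rz <- 3.2 * rb
  ctr <- dims * vs / 2
  if (2.2 * rb > dims[1] * vs || 2.05 * rz > dims[3] * vs)
    stop("resolution error: body does not fit the grid; enlarge grid or voxel size")

  labels <- array(0L, dims)
  everywhere <- array(TRUE, dims)
  b <- .vox_ellipsoid(labels, everywhere, dims, vs, ctr, c(rb, rb, rz), 1L)
  labels <- b$labels
  body_mask <- labels == 1L

  region_names <- c("body", names(spec$organ_masses_g), "tumor")
  ids <- stats::setNames(seq_along(region_names), region_names)
  counts <- stats::setNames(integer(length(region_names)), region_names)
  counts["body"] <- b$count

  layout <- .phantom_layout()
  claim <- body_mask  # organs may only claim body (remainder) voxels

  place_scaled <- function(labels, claim, target_g, vox_fun) {
    # secant search on the linear scale so achieved mass hits the target
    target_n <- mm3(target_g) / vs^3
    s <- 1; res <- vox_fun(labels, claim, s)
    if (res$count < 1)
      stop("resolution error: region occupies no voxel; decrease voxel_size_mm")
    for (it in 1:6) {
      err <- res$count / target_n
      if (abs(err - 1) <= min(0.01, mass_tol / 2)) break
      s <- s * err^(-1/3)
      res <- vox_fun(labels, claim, s)
    }
    res
  }

  for (org in names(spec$organ_masses_g)) {
    if (org %in% c("bone", "marrow")) next
    ly <- layout[[org]]
    if (is.null(ly))  # unknown organ: default to an axial sphere mid-body
      ly <- list(shape = "ellipsoid", ratio = c(1, 1, 1), pos = c(0, -0.1, -0.6))
    m <- spec$organ_masses_g[[org]]
    center <- ctr + ly$pos * c(rb, rb, rz)
    if (ly$shape == "pair") {
      s0 <- (mm3(m / 2) * 3 / (4 * pi * prod(ly$ratio)))^(1/3)
      res <- place_scaled(labels, claim, m, function(lb, cl, s) {
        r1 <- .vox_ellipsoid(lb, cl, dims, vs,
                             ctr + c(ly$pos[1], ly$pos[2], ly$pos[3]) * c(rb, rb, rz),
                             s * s0 * ly$ratio, ids[[org]])
        r2 <- .vox_ellipsoid(r1$labels, cl, dims, vs,
                             ctr + c(-ly$pos[1], ly$pos[2], ly$pos[3]) * c(rb, rb, rz),
                             s * s0 * ly$ratio, ids[[org]])
        list(labels = r2$labels, count = r1$count + r2$count)
      })
    } else {
      s0 <- (mm3(m) * 3 / (4 * pi * prod(ly$ratio)))^(1/3)
      res <- place_scaled(labels, claim, m, function(lb, cl, s)
        .vox_ellipsoid(lb, cl, dims, vs, center, s * s0 * ly$ratio, ids[[org]]))
    }
    labels <- res$labels
    counts[org] <- res$count
    claim <- claim & labels == 1L
  }

  # skeleton: dorsal z-cylinder with the red marrow as a coaxial core.
  # Cylinder masses are calibrated in two steps (radius, then slab count)
  # because per-slab voxel counts are integers: a thin core could otherwise
  # not hit its target mass at coarse resolutions.
  if (all(c("bone", "marrow") %in% names(spec$organ_masses_g))) {
    Lz0 <- 1.7 * rz
    cxy <- ctr[1:2] + c(0, 0.66 * rb)
    xi2 <- ((seq_len(dims[1]) - 0.5) * vs - cxy[1])^2
    yi2 <- ((seq_len(dims[2]) - 0.5) * vs - cxy[2])^2
    R2 <- outer(xi2, yi2, "+")
    k0 <- which.min(abs((seq_len(dims[3]) - 0.5) * vs - ctr[3]))
    # slab order: outward from the body centre
    slab_order <- order(abs(seq_len(dims[3]) - k0))
    zc <- (seq_len(dims[3]) - 0.5) * vs
    pick_rod <- function(claimable, target_g, radii, r_in) {
      # per-slab claimable counts for each candidate radius, then the slab
      # set (grown outward) whose cumulative count best matches the target
      target_n <- mm3(target_g) / vs^3
      best <- NULL
      for (r in radii) {
        m <- R2 <= r^2 & R2 > r_in^2
        if (!any(m)) next
        per <- vapply(slab_order, function(k) {
          cl <- claimable[, , k]; dim(cl) <- dim(m); sum(m & cl)
        }, integer(1))
        cum <- cumsum(per)
        j <- which.min(abs(cum - target_n))
        if (is.null(best) || abs(cum[j] - target_n) < best$err)
          best <- list(r = r, slabs = slab_order[seq_len(j)],
                       err = abs(cum[j] - target_n))
      }
      if (is.null(best) || best$err > mass_tol * target_n)
        stop("resolution error: skeleton rod cannot match its mass; decrease voxel_size_mm")
      best
    }
    vox_rod <- function(lb, claimable, rod, r_in, id) {
      m <- R2 <= rod$r^2 & R2 > r_in^2
      n <- 0L
      for (k in rod$slabs) {
        sub <- lb[, , k]; cl <- claimable[, , k]
        dim(sub) <- dim(m); dim(cl) <- dim(m)
        take <- m & cl
        sub[take] <- id
        lb[, , k] <- sub
        n <- n + sum(take)
      }
      list(labels = lb, count = n)
    }
    r_in0 <- sqrt(mm3(spec$organ_masses_g[["marrow"]]) / (pi * Lz0))
    rod_m <- pick_rod(claim, spec$organ_masses_g[["marrow"]],
                      r_in0 * seq(0.7, 1.6, by = 0.1), 0)
    res_m <- vox_rod(labels, claim, rod_m, 0, ids[["marrow"]])
    labels <- res_m$labels
    counts["marrow"] <- res_m$count
    claim <- claim & labels == 1L
    r_out0 <- sqrt(rod_m$r^2 + mm3(spec$organ_masses_g[["bone"]]) / (pi * Lz0))
    rod_b <- pick_rod(claim, spec$organ_masses_g[["bone"]],
                      r_out0 * seq(0.8, 1.8, by = 0.1), rod_m$r)
    res_b <- vox_rod(labels, claim, rod_b, rod_m$r, ids[["bone"]])
    labels <- res_b$labels
    counts["bone"] <- res_b$count
    claim <- claim & labels == 1L
  }

  # tumour: 1:2:2 ellipsoid outside the skin on the right flank, short
  # semi-axis a along +x, attached at the body surface
  a0 <- (mm3(spec$tumor_mass_g) * 3 / (16 * pi))^(1/3)
  zt_frac <- -0.30
  zt <- ctr[3] + zt_frac * rz
  x_surf <- ctr[1] + rb * sqrt(max(0, 1 - zt_frac^2))
  outside <- !body_mask
  res_t <- place_scaled(labels, outside, spec$tumor_mass_g, function(lb, cl, s)
    .vox_ellipsoid(lb, cl, dims, vs, c(x_surf + s * a0, ctr[2], zt),
                   s * a0 * c(1, 2, 2), ids[["tumor"]]))
  labels <- res_t$labels
  counts["tumor"] <- res_t$count

  counts["body"] <- sum(labels == 1L)
  achieved <- counts * vox_mass
  targets <- c(body = spec$body_weight_g - sum(spec$organ_masses_g),
               spec$organ_masses_g, tumor = spec$tumor_mass_g)
  organs_only <- setdiff(region_names, "body")
  off <- abs(achieved[organs_only] / targets[organs_only] - 1)
  if (any(off > mass_tol))
    stop("mass calibration failed for: ",
         paste(sprintf("%s (%.1f%%)", organs_only[off > mass_tol],
                       100 * off[off > mass_tol]), collapse = ", "),
         "; decrease voxel_size_mm")
  total <- sum(achieved)
  if (abs(total - (spec$body_weight_g + spec$tumor_mass_g)) >
      0.01 * (spec$body_weight_g + spec$tumor_mass_g))
    warning("voxelised total mass deviates >1 % from body weight + tumour")

  structure(list(labels = labels,
                 region_table = data.frame(
                   id = unname(ids), region = region_names,
                   target_mass_g = unname(targets[region_names]),
                   achieved_mass_g = unname(achieved[region_names])),
                 voxel_size_mm = vs,
                 density_g_cm3 = spec$density_g_cm3,
                 provenance = spec),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  cat(sprintf("<voxel_phantom> %s voxels @ %.3g mm, %d regions, %.1f g total\n",
              paste(dim(x$labels), collapse = "x"), x$voxel_size_mm,
              nrow(x$region_table), sum(x$region_table$achieved_mass_g)))
  print(x$region_table, row.names = FALSE)
  invisible(x)
}

#' Region masses of a voxel phantom
#' @param phantom a `voxel_phantom`.
#' @return named numeric vector of achieved masses in grams.
#' @export
region_masses <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  stats::setNames(phantom$region_table$achieved_mass_g, phantom$region_table$region)
}

#' Centroid distances between phantom regions
#'
#' Euclidean distances (mm) between region centroids; a symmetric matrix
#' with a zero diagonal, useful as a plausibility diagnostic for cross-organ
#' S-factors (dose falls off with distance).
#'
#' @param phantom a `voxel_phantom`.
#' @return symmetric numeric matrix (mm) with region-name dimnames.
#' @export
region_centroid_distances <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  rt <- phantom$region_table
  vs <- phantom$voxel_size_mm
  cent <- t(vapply(rt$id, function(id) {
    w <- which(phantom$labels == id, arr.ind = TRUE)
    (colMeans(w) - 0.5) * vs
  }, numeric(3)))
  d <- as.matrix(stats::dist(cent))
  dimnames(d) <- list(rt$region, rt$region)
  d
}

#' Export / import a voxel phantom
#'
#' Writes the label array as a flat binary file (int32, x fastest, 0-based
#' voxel indices) with a JSON sidecar carrying the grid, voxel size, density
#' and region table.
#'
#' @param phantom a `voxel_phantom`.
#' @param path base path; `<path>.bin` and `<path>.json` are written.
#' @return the base path, invisibly.
#' @export
write_phantom <- function(phantom, path) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  con <- file(paste0(path, ".bin"), "wb")
  on.exit(close(con))
  writeBin(as.integer(phantom$labels), con, size = 4L, endian = "little")
  jsonlite::write_json(list(
    grid = dim(phantom$labels), voxel_size_mm = phantom$voxel_size_mm,
    density_g_cm3 = phantom$density_g_cm3, order = "x-fastest",
    regions = phantom$region_table), paste0(path, ".json"),
    auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_phantom
#' @export
read_phantom <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dims <- as.integer(meta$grid)
  con <- file(paste0(path, ".bin"), "rb")
  on.exit(close(con))
  lab <- readBin(con, "integer", n = prod(dims), size = 4L, endian = "little")
  structure(list(labels = array(lab, dims),
                 region_table = as.data.frame(meta$regions),
                 voxel_size_mm = meta$voxel_size_mm,
                 density_g_cm3 = meta$density_g_cm3,
                 provenance = NULL),
            class = "voxel_phantom")
}
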