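#' Synthetic studies of cerebrocerebellar labeling
#'
#' The generator emulates the design of a mono-trans-synaptic tracing
#' study: for each cortical origin a fixed number of labeled mossy-fiber
#' terminals is distributed over (side, lobule) cells of the cerebellum
#' according to origin-specific laterality and lobule-mixing proportions,
#' perturbed per animal; point coordinates are placed inside per-lobule
#' cuboid regions by a uniform (CSR) or Thomas-type clustered process;
#' terminals are assigned to alternating AldoC stripes with a
#' configurable bias; and a linked table of precerebellar cell counts is
#' emitted so that the pooled terminals-per-cell ratio matches a
#' configured value (about 50 mossy fibers per precerebellar neuron).
#'
#' @name synthetic
NULL

# ---- regions -------------------------------------------------------------

#' Axis-aligned cuboid region
#'
#' @param xlim,ylim,zlim Numeric length-2 vectors (um), strictly
#'   increasing.
#' @return A `cuboid` object with elements `lo`, `hi`.
#' @export
cuboid <- function(xlim, ylim, zlim) {
  lo <- c(x = xlim[1], y = ylim[1], z = zlim[1])
  hi <- c(x = xlim[2], y = ylim[2], z = zlim[2])
  if (any(!is.finite(c(lo, hi))) || any(hi - lo <= 0))
    stop("degenerate region: all side lengths must be positive and finite")
  structure(list(lo = lo, hi = hi), class = "cuboid")
}

#' @rdname cuboid
#' @param region A `cuboid`.
#' @return `cuboid_volume`: volume in um^3.
#' @export
cuboid_volume <- function(region) {
  stopifnot(inherits(region, "cuboid"))
  prod(region$hi - region$lo)
}

.in_cuboid <- function(xyz, region) {
  xyz[, 1] >= region$lo[1] & xyz[, 1] <= region$hi[1] &
  xyz[, 2] >= region$lo[2] & xyz[, 2] <= region$hi[2] &
  xyz[, 3] >= region$lo[3] & xyz[, 3] <= region$hi[3]
}

#' Per-lobule cuboid geometry for synthetic studies
#'
#' Lobule shapes are not modelled; each lobule-side is an axis-aligned
#' cuboid with mediolateral:dorsoventral:rostrocaudal aspect ratio 2:1:1
#' and volume equal to half the lobule volume (one hemisphere). The two
#' sides abut the midline (x = 0, ipsilateral negative x); lobules are
#' staggered along z so regions never overlap.
#'
#' @param atlas A `cerebellar_atlas`.
#' @param gap_um Rostrocaudal gap between consecutive lobule blocks (um).
#' @return Named list per lobule: `a` (cuboid height, um), `z0` (z
#'   offset), and `cuboid`s `ipsilateral`, `contralateral`.
#' @export
lobule_regions <- function(atlas = default_atlas(), gap_um = 200) {
  regions <- list()
  z0 <- 0
  for (i in seq_len(nrow(atlas))) {
    v_half_um3 <- atlas$volume_mm3[i] * 1e9 / 2
    a <- (v_half_um3 / 2)^(1 / 3)   # dims 2a x a x a => volume 2a^3
    regions[[atlas$lobule[i]]] <- list(
      a = a, z0 = z0,
      ipsilateral = cuboid(c(-2 * a, 0), c(0, a), c(z0, z0 + a)),
      contralateral = cuboid(c(0, 2 * a), c(0, a), c(z0, z0 + a)))
    z0 <- z0 + a + gap_um
  }
  regions
}

#' Default synthetic stripe map
#'
#' Splits every lobule's full mediolateral extent (both sides) into
#' `2 * n_stripes` equal alternating intervals starting with AldoC+ at
#' the ipsilateral edge, so that the AldoC+ and AldoC- extents are equal
#' on each side. This is a synthetic stand-in for a measured zebrin
#' expression map.
#'
#' @param atlas A `cerebellar_atlas`.
#' @param n_stripes Stripes per label per side.
#' @param regions Geometry from [lobule_regions()].
#' @return A `stripe_map`.
#' @export
default_stripe_map <- function(atlas = default_atlas(), n_stripes = 4,
                               regions = lobule_regions(atlas)) {
  entries <- lapply(atlas$lobule, function(lb) {
    g <- regions[[lb]]
    stripe_entry(lb,
                 boundaries = seq(-2 * g$a, 2 * g$a,
                                  length.out = 2 * n_stripes + 1),
                 first_label = "AldoC+",
                 z_min = g$z0, z_max = g$z0 + g$a)
  })
  stripe_map(entries)
}

# ---- point processes -----------------------------------------------------

#' Simulate complete spatial randomness (CSR)
#'
#' `n` points i.i.d. uniform in an axis-aligned cuboid — the homogeneous
#' Poisson null conditioned on the observed count, as used by the CSR
#' Monte Carlo test.
#'
#' @param n Number of points (>= 0).
#' @param region A `cuboid`.
#' @param seed Optional integer; when given, the draw is a pure function
#'   of `(n, region, seed)`.
#' @return Numeric matrix with columns `x`, `y`, `z` (um).
#' @export
simulate_csr <- function(n, region, seed = NULL) {
  stopifnot(inherits(region, "cuboid"), n >= 0)
  if (!is.null(seed)) set.seed(seed)
  m <- cbind(x = runif(n, region$lo[1], region$hi[1]),
             y = runif(n, region$lo[2], region$hi[2]),
             z = runif(n, region$lo[3], region$hi[3]))
  m
}

#' Simulate a Thomas-type cluster process
#'
#' Poisson parents with intensity `parent_intensity` per mm^3, a
#' Poisson(`mean_offspring`) number of offspring per parent, and
#' isotropic Gaussian displacements (sd `sigma` um per axis). Offspring
#' falling outside the region have their displacement redrawn
#' (resample-inside boundary handling), so the expected retained count is
#' `parent_intensity * volume_mm3 * mean_offspring` up to the slight
#' interior-intensity inflation this rule causes near edges.
#'
#' @param region A `cuboid`.
#' @param parent_intensity Parents per mm^3 (> 0).
#' @param mean_offspring Mean offspring per parent (> 0).
#' @param sigma Offspring displacement sd per axis (um, > 0).
#' @param seed Optional integer seed.
#' @return Numeric matrix with columns `x`, `y`, `z` (um) and attribute
#'   `parents` (parent coordinates).
#' @export
simulate_clustered <- function(region, parent_intensity, mean_offspring,
                               sigma, seed = NULL) {
  stopifnot(inherits(region, "cuboid"))
  if (!is.finite(sigma) || sigma <= 0) stop("sigma must be positive")
  if (parent_intensity <= 0 || mean_offspring <= 0)
    stop("parent_intensity and mean_offspring must be positive")
  if (!is.null(seed)) set.seed(seed)
  vol_mm3 <- cuboid_volume(region) / 1e9
  n_par <- stats::rpois(1, parent_intensity * vol_mm3)
  parents <- simulate_csr(n_par, region)
  n_off <- if (n_par) stats::rpois(n_par, mean_offspring) else integer(0)
  pts <- .displace_offspring(parents[rep(seq_len(n_par), n_off), , drop = FALSE],
                             sigma, region)
  attr(pts, "parents") <- parents
  pts
}

# Gaussian displacement with resample-inside boundary handling.
.displace_offspring <- function(centers, sigma, region, max_iter = 1000) {
  n <- nrow(centers)
  pts <- centers + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
  colnames(pts) <- c("x", "y", "z")
  for (it in seq_len(max_iter)) {
    bad <- which(!.in_cuboid(pts, region))
    if (!length(bad)) break
    pts[bad, ] <- centers[bad, , drop = FALSE] +
      matrix(stats::rnorm(3 * length(bad), 0, sigma), ncol = 3)
  }
  bad <- which(!.in_cuboid(pts, region))
  if (length(bad)) pts[bad, ] <- centers[bad, , drop = FALSE]
  pts
}

# Clustered placement of exactly n points: parents Poisson, each point
# attached to a uniformly chosen parent (used by simulate_study where the
# multinomial allocation fixes the count).
.clustered_n <- function(n, region, parent_intensity, sigma) {
  if (n == 0) {
    m <- matrix(numeric(0), ncol = 3, dimnames = list(NULL, c("x", "y", "z")))
    return(m)
  }
  vol_mm3 <- cuboid_volume(region) / 1e9
  n_par <- max(1L, stats::rpois(1, parent_intensity * vol_mm3))
  parents <- simulate_csr(n_par, region)
  pick <- sample.int(n_par, n, replace = TRUE)
  .displace_offspring(parents[pick, , drop = FALSE], sigma, region)
}

# ---- study configuration -------------------------------------------------

#' Default lobule mixing proportions per cortical origin
#'
#' Rows are origins, columns the 16 lobules; each row is a simplex. The
#' profiles emulate the qualitative biases of the tracing study: motor
#' (M1) input biased to hemispheric lobules (crus II, Sim, PM), S1 to
#' crus I/PM/Cop/IV-V, association (PPC) spread over crus I, IV/V-VI and
#' paraflocculus, V1 dominated by the paraflocculus, A1 biased to the
#' vermis, AuD to crus I/II.
#'
#' @return 6 x 16 row-stochastic matrix.
#' @export
default_mixing <- function() {
  w <- rbind(
    M1  = c(0.5, 0.5, 1, 8, 10, 0.5, 1, 1, 3, 16, 12, 20, 14, 0.5, 6, 2),
    S1  = c(0.5, 1, 2, 10, 4, 0.5, 2, 1, 1, 4, 18, 4, 16, 14, 14, 4),
    PPC = c(0.5, 0.5, 1, 10, 12, 1, 1, 2, 2, 4, 19, 5, 4, 0.5, 19, 4),
    V1  = c(0.2, 0.3, 0.5, 3, 5, 0.5, 1, 2, 1, 3, 16, 4, 3, 0.5, 44, 4),
    A1  = c(1, 2, 9, 12, 8, 1, 3, 6, 2, 3, 8, 7, 4, 0.5, 8, 3),
    AuD = c(0.5, 1, 1, 7, 7, 0.5, 2, 3, 1, 4, 15, 8, 4, 0.5, 8, 3))
  colnames(w) <- .LOBULE_IDS
  sweep(w, 1, rowSums(w), "/")
}

#' Configuration of a synthetic tracing study
#'
#' Defaults follow the study conditions: three animals per cortical
#' origin; contralateral fractions 0.85 (S1), 0.74 (M1, V1, A1 — primary
#' areas), 0.58 (PPC, AuD — association/secondary areas); about 50 mossy
#' fiber terminals per precerebellar cell (between-animal sd 12); 73% of
#' precerebellar cells pontine; per-origin totals of order 10^4 for
#' M1/S1 down to ~580 for AuD.
#'
#' @param origins Cortical origin labels.
#' @param n_terminals Named per-origin terminal totals.
#' @param contra_fraction Named per-origin contralateral fractions in
#'   \[0, 1\].
#' @param mixing Row-stochastic origin x lobule matrix.
#' @param concentration Dirichlet concentration for per-animal
#'   perturbation of the mixing simplex (larger = less animal-to-animal
#'   variability; Inf = none).
#' @param clustering `list(type = "none")` or `list(type = "clustered",
#'   parent_intensity = per mm^3, sigma = um)` for within-lobule Thomas
#'   clustering.
#' @param stripe_bias Probability that a terminal falls in an AldoC+
#'   stripe (0.5 = area-proportional, no bias).
#' @param mf_per_cell,mf_per_cell_sd Mossy fibers per precerebellar cell:
#'   mean and between-animal sd.
#' @param pontine_share Fraction of precerebellar cells in the pontine
#'   nuclei.
#' @param seed Default RNG seed for [simulate_study()].
#' @return A `sim_config` list (validated).
#' @export
simulation_config <- function(origins = .ORIGINS,
                              n_terminals = c(M1 = 10000, S1 = 10000,
                                              PPC = 3000, V1 = 2000,
                                              A1 = 1500, AuD = 580),
                              contra_fraction = c(M1 = 0.74, S1 = 0.85,
                                                  PPC = 0.58, V1 = 0.74,
                                                  A1 = 0.74, AuD = 0.58),
                              mixing = default_mixing(),
                              concentration = 30,
                              clustering = list(type = "none"),
                              stripe_bias = 0.5,
                              mf_per_cell = 50, mf_per_cell_sd = 12,
                              pontine_share = 0.73,
                              seed = 1L) {
  cfg <- list(origins = origins,
              n_terminals = n_terminals[origins],
              contra_fraction = contra_fraction[origins],
              mixing = mixing[origins, , drop = FALSE],
              concentration = concentration,
              clustering = clustering,
              stripe_bias = stripe_bias,
              mf_per_cell = mf_per_cell, mf_per_cell_sd = mf_per_cell_sd,
              pontine_share = pontine_share,
              seed = as.integer(seed))
  validate_config(cfg)
}

validate_config <- function(cfg) {
  with(cfg, {
    if (!length(origins)) stop("config: at least one origin required")
    if (anyNA(n_terminals) || any(n_terminals <= 0) ||
        any(n_terminals != round(n_terminals)))
      stop("config: n_terminals must be positive integers for every origin")
    if (anyNA(contra_fraction) || any(contra_fraction < 0 | contra_fraction > 1))
      stop("config: contra_fraction must lie in [0, 1]")
    if (nrow(mixing) != length(origins) ||
        any(abs(rowSums(mixing) - 1) > 1e-9) || any(mixing < 0))
      stop("config: mixing rows must be simplexes over the lobules")
    if (concentration <= 0) stop("config: concentration must be positive")
    if (stripe_bias < 0 || stripe_bias > 1)
      stop("config: stripe_bias must lie in [0, 1]")
    if (mf_per_cell <= 0 || mf_per_cell_sd < 0)
      stop("config: mf_per_cell must be positive")
    if (pontine_share < 0 || pontine_share > 1)
      stop("config: pontine_share must lie in [0, 1]")
    if (!clustering$type %in% c("none", "clustered"))
      stop("config: clustering$type must be 'none' or 'clustered'")
  })
  structure(cfg, class = "sim_config")
}

.EXTRAPONTINE_NUCLEI <- c("RtTg", "LRt", "Sp5I", "Mx", "VN", "CN", "Ru")
.EXTRAPONTINE_W <- c(0.30, 0.20, 0.15, 0.05, 0.15, 0.10, 0.05)

.rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha)
  if (sum(g) == 0) return(alpha / sum(alpha))
  g / sum(g)
}

# Sample x uniformly over the union of intervals of `label` within the
# side's mediolateral extent of a stripe entry.
.sample_stripe_x <- function(n, entry, side, label) {
  b <- entry$boundaries
  lab <- .entry_labels(entry)
  lo <- b[-length(b)]; hi <- b[-1]
  keep <- lab == label & (if (side == "ipsilateral") hi <= 0 else lo >= 0)
  lo <- lo[keep]; hi <- hi[keep]
  if (!length(lo)) return(NULL)
  len <- hi - lo
  pick <- sample.int(length(lo), n, replace = TRUE, prob = len)
  stats::runif(n, lo[pick], hi[pick])
}

#' Simulate a full synthetic tracing study
#'
#' Per animal and origin: lobule mixing is drawn from a Dirichlet
#' perturbation of the configured simplex (concentration
#' `config$concentration`), the per-animal contralateral fraction from a
#' Beta distribution centred on the configured value, and the origin's
#' terminal total is allocated multinomially over (side, lobule) cells.
#' Coordinates are placed in the per-lobule cuboids by CSR or a
#' Thomas-type clustered process; stripe labels come from the default
#' synthetic stripe map, with `stripe_bias` applied by resampling the
#' mediolateral coordinate within the chosen stripe class. Precerebellar
#' cell counts are emitted per animal so total terminals / total cells
#' matches `config$mf_per_cell` up to the configured dispersion.
#'
#' @param config A `sim_config`.
#' @param n_animals Animals per origin (the study used three).
#' @param atlas A `cerebellar_atlas`.
#' @param seed Integer seed; defaults to `config$seed`. The study is a
#'   pure function of `(config, n_animals, seed)`.
#' @return A `mossy_study` list: `terminals` (data frame: `animal`,
#'   `origin`, `x`, `y`, `z`, `side`, `lobule`, `stripe`), `cells` (data
#'   frame: `animal`, `origin`, `nucleus`, `category`, `side`,
#'   `label_mode`, `n_cells`), `ground_truth` (realized per-animal mixing
#'   simplexes, contralateral fractions, MF-per-cell ratios), plus the
#'   atlas, regions and stripe map used.
#' @export
simulate_study <- function(config, n_animals = 3, atlas = default_atlas(),
                           seed = config$seed) {
  config <- validate_config(unclass(config))
  stopifnot(n_animals >= 1)
  set.seed(seed)
  regions <- lobule_regions(atlas)
  smap <- default_stripe_map(atlas, regions = regions)
  entries <- stats::setNames(smap$entries,
                             vapply(smap$entries, `[[`, "", "lobule"))
  lobs <- atlas$lobule
  term_chunks <- list(); cell_chunks <- list()
  gt_mix <- list(); gt_contra <- list(); gt_ratio <- list()

  for (org in config$origins) {
    p0 <- config$mixing[org, lobs]
    for (an in seq_len(n_animals)) {
      animal <- sprintf("%s_a%d", org, an)
      p <- if (is.finite(config$concentration))
        .rdirichlet1(config$concentration * p0) else p0
      cf0 <- config$contra_fraction[[org]]
      cf <- if (cf0 %in% c(0, 1)) cf0 else
        stats::rbeta(1, cf0 * 50, (1 - cf0) * 50)
      # multinomial allocation over (side, lobule)
      probs <- c(p * (1 - cf), p * cf)   # ipsi block then contra block
      alloc <- as.integer(stats::rmultinom(1, config$n_terminals[[org]], probs))
      names(alloc) <- c(paste0("ipsilateral.", lobs),
                        paste0("contralateral.", lobs))
      for (side in .SIDES) {
        for (j in seq_along(lobs)) {
          n_lj <- alloc[[paste0(side, ".", lobs[j])]]
          if (n_lj == 0) next
          reg <- regions[[lobs[j]]][[side]]
          pts <- if (config$clustering$type == "clustered")
            .clustered_n(n_lj, reg, config$clustering$parent_intensity,
                         config$clustering$sigma)
          else simulate_csr(n_lj, reg)
          if (config$stripe_bias != 0.5) {
            want_plus <- stats::runif(n_lj) < config$stripe_bias
            for (lb in c("AldoC+", "AldoC-")) {
              k <- which(want_plus == (lb == "AldoC+"))
              if (length(k)) {
                xs <- .sample_stripe_x(length(k), entries[[lobs[j]]], side, lb)
                if (!is.null(xs)) pts[k, "x"] <- xs
              }
            }
          }
          term_chunks[[length(term_chunks) + 1L]] <- data.frame(
            animal = animal, origin = org,
            x = pts[, "x"], y = pts[, "y"], z = pts[, "z"],
            side = side, lobule = lobs[j], stringsAsFactors = FALSE)
        }
      }
      n_a <- config$n_terminals[[org]]
      ratio <- max(5, stats::rnorm(1, config$mf_per_cell, config$mf_per_cell_sd))
      n_cells <- max(1L, as.integer(round(n_a / ratio)))
      n_pont <- stats::rbinom(1, n_cells, config$pontine_share)
      n_ep <- as.integer(stats::rmultinom(1, n_cells - n_pont, .EXTRAPONTINE_W))
      cell_chunks[[length(cell_chunks) + 1L]] <- data.frame(
        animal = animal, origin = org,
        nucleus = c("Pn", .EXTRAPONTINE_NUCLEI),
        category = c("pontine", rep("extra-pontine", length(.EXTRAPONTINE_NUCLEI))),
        side = "ipsilateral", label_mode = "anterograde",
        n_cells = c(n_pont, n_ep), stringsAsFactors = FALSE)
      gt_mix[[animal]] <- stats::setNames(as.numeric(p), lobs)
      gt_contra[[animal]] <- cf
      gt_ratio[[animal]] <- n_a / sum(c(n_pont, n_ep))
    }
  }
  terminals <- do.call(rbind, term_chunks)
  rownames(terminals) <- NULL
  terminals$stripe <- assign_stripe(terminals, smap)
  cells <- do.call(rbind, cell_chunks)
  rownames(cells) <- NULL
  structure(list(terminals = terminals, cells = cells,
                 ground_truth = list(mixing = gt_mix,
                                     contra_fraction = unlist(gt_contra),
                                     mf_per_cell = unlist(gt_ratio),
                                     config = config),
                 atlas = atlas, regions = regions, stripe_map = smap,
                 seed = seed, n_animals = n_animals),
            class = "mossy_study")
}

#' @export
print.mossy_study <- function(x, ...) {
  cat("Synthetic cerebrocerebellar study\n")
  cat("  terminals:", nrow(x$terminals), "from",
      length(unique(x$terminals$origin)), "origins x",
      x$n_animals, "animals\n")
  cat("  precerebellar cells:", sum(x$cells$n_cells),
      sprintf("(%.0f%% pontine)\n",
              100 * sum(x$cells$n_cells[x$cells$category == "pontine"]) /
                sum(x$cells$n_cells)))
  cat("  pooled MF/cell ratio:",
      format(nrow(x$terminals) / sum(x$cells$n_cells), digits = 3), "\n")
  invisible(x)
}
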