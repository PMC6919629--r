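# Synthetic-data generators: every input of the analysis pipeline can be
# produced with the statistical structure the real data are assumed to
# have, so all downstream stages are testable without downloads. All
# generators are deterministic under a fixed seed.

.aa20 <- names(.residue_mono)

.with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv()))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old,
                                      envir = globalenv()))
    set.seed(seed)
  }
  force(expr)
}

.random_aa <- function(n) paste(sample(.aa20, n, replace = TRUE),
                                collapse = "")

.has_planted_motifs <- function(sequence, max_basic_run = 3L) {
  nrow(scan_cleavage_sites(sequence)) > 0L ||
    nrow(predict_amidation_sites(sequence,
                                 max_basic_run = max_basic_run)) > 0L
}

# rejection-sample a sequence containing no cleavage motif and no
# C-terminal amidation context
.motif_free_sequence <- function(len, max_tries = 1000L) {
  for (i in seq_len(max_tries)) {
    s <- .random_aa(len)
    if (!.has_planted_motifs(s)) return(s)
  }
  stop("failed to generate a motif-free sequence; try a shorter length",
       call. = FALSE)
}

#' Synthetic proteome with planted amidation sites
#'
#' Generates motif-free decoy proteins (by rejection) plus precursors with
#' one planted site each of the requested class. All records are marked
#' signal-peptide-positive so the screen's signal subset is the whole set;
#' planted motifs are verified after embedding (re-drawn on accidental
#' extra sites), making planted-truth recovery exact.
#'
#' @param n_decoys Number of motif-free decoys.
#' @param planted_classes Character vector over `"INTERNAL_PC"`,
#'   `"INTERNAL_FURIN"`, `"CTERM_GLY"`, `"CTERM_GLY_BASIC"`; one precursor
#'   is planted per element.
#' @param decoy_length,scaffold_length Sequence lengths.
#' @param seed Random seed.
#' @return list with `records` (list of [protein_record()]) and `truth`
#'   (data.frame: id, class, glycine_index).
#' @export
make_proteome <- function(n_decoys = 90L, planted_classes = character(),
                          decoy_length = 80L, scaffold_length = 60L,
                          seed = 1L) {
  valid <- c("INTERNAL_PC", "INTERNAL_FURIN", "CTERM_GLY", "CTERM_GLY_BASIC")
  if (!all(planted_classes %in% valid))
    stop("unknown planted class", call. = FALSE)
  if (scaffold_length < 10L)
    stop("scaffold too short to embed a site", call. = FALSE)
  .with_seed(seed, {
    records <- vector("list", n_decoys + length(planted_classes))
    truth <- list()
    for (i in seq_len(n_decoys)) {
      records[[i]] <- protein_record(sprintf("decoy_%03d", i),
                                     .motif_free_sequence(decoy_length),
                                     has_signal_peptide = TRUE)
    }
    for (p in seq_along(planted_classes)) {
      cls <- planted_classes[p]
      repeat {
        scaffold <- .motif_free_sequence(scaffold_length)
        half <- as.integer(scaffold_length / 2)
        seqn <- switch(cls,
          CTERM_GLY = paste0(scaffold, "G"),
          CTERM_GLY_BASIC = paste0(scaffold, "G",
                                   paste(sample(c("K", "R"),
                                                sample(1:3, 1),
                                                replace = TRUE),
                                         collapse = "")),
          INTERNAL_PC = paste0(substr(scaffold, 1L, half), "GKR",
                               substr(scaffold, half + 1L, scaffold_length)),
          INTERNAL_FURIN = paste0(substr(scaffold, 1L, half), "GRAKR",
                                  substr(scaffold, half + 1L,
                                         scaffold_length)))
        found <- predict_amidation_sites(seqn)
        if (nrow(found) == 1L && found$class == cls) break
      }
      idx <- n_decoys + p
      records[[idx]] <- protein_record(sprintf("planted_%s_%02d",
                                               tolower(cls), p),
                                       seqn, has_signal_peptide = TRUE)
      truth[[p]] <- data.frame(id = records[[idx]]$id, class = cls,
                               glycine_index = found$glycine_index)
    }
    truth <- if (length(truth) > 0L) do.call(rbind, truth) else
      data.frame(id = character(), class = character(),
                 glycine_index = integer())
    list(records = records, truth = truth)
  })
}

#' Worked-example precursors of the three identified amidated peptides
#'
#' Three synthetic precursor proteins carrying the C-terminal contexts of
#' the identified amidated peptides: an intact terminus ending -GRRR
#' (trimming yields VLYPNDPAAYAAYAPGTGGGATI-amide, "GATI-amide"), an
#' intact terminus ending -GR (yields PLVPAAA-amide), and an internal
#' cleavage followed by Arg/His removal (yields GELNPAGGQLPG-amide;
#' requires `his_trim = TRUE` during processing). Filler segments are
#' fixed motif-free sequences, so the constructor is deterministic. These
#' are synthetic stand-ins for the database precursor entries, not the
#' database sequences themselves.
#'
#' @return list with `records` (3 [protein_record()]s), `peptides` (the
#'   three amidated peptide sequences) and `processing` (the
#'   [processing_config()] reproducing them).
#' @export
example_amidated_precursors <- function() {
  filler1 <- "MNSTLAEVDFAQPWYTILVSE"
  filler2 <- "MTEALQNDFSVPYWIHLASTE"
  filler3 <- "MQDVLANSEFTPYWILHSTAE"
  records <- list(
    protein_record("pre_GATI",
                   paste0(filler1, "KR", "VLYPNDPAAYAAYAPGTGGGATIGRRR"),
                   has_signal_peptide = TRUE),
    protein_record("pre_PLVPAAA",
                   paste0(filler2, "KR", "PLVPAAAGR"),
                   has_signal_peptide = TRUE),
    protein_record("pre_GELN",
                   paste0(filler3, "KR", "GELNPAGGQLPGGHRKRA"),
                   has_signal_peptide = TRUE))
  list(records = records,
       peptides = c("VLYPNDPAAYAAYAPGTGGGATI", "PLVPAAA", "GELNPAGGQLPG"),
       processing = processing_config(his_trim = TRUE))
}

#' Synthetic PSM replicate sets
#'
#' Builds `n_replicates` peptide-spectrum-match tables, each containing
#' every planted amidated peptide at its theoretical monoisotopic mass
#' perturbed by uniform(+/- `noise_ppm`) relative noise, plus decoy PSMs
#' whose masses are rejection-sampled to avoid every candidate matching
#' window by at least 3x the screen tolerance (screen specificity on this
#' fixture is therefore a hard guarantee, not a probabilistic one).
#'
#' @param planted data.frame with `peptide` (amidated form) and
#'   `parent_protein_id`, or a character vector of peptides.
#' @param proteome Protein records used to enumerate the candidate windows
#'   decoys must avoid (see [build_amidation_candidates()]).
#' @param n_replicates Number of samples (default 6).
#' @param noise_ppm Mass noise half-width in ppm (default 3).
#' @param n_decoys Decoy PSMs per replicate (default 50).
#' @param tol_ppm Screen tolerance the decoys must clear 3x (default 10).
#' @param processing,digest Candidate-generation configuration (must match
#'   the screen's).
#' @param seed Random seed.
#' @return data.frame of PSMs: `sample_id`, `peptide_sequence` (database,
#'   i.e. glycine-extended, form for planted rows), `observed_neutral_mass`,
#'   `parent_protein_id`, `is_decoy`.
#' @export
make_psm_sets <- function(planted, proteome, n_replicates = 6L,
                          noise_ppm = 3, n_decoys = 50L, tol_ppm = 10,
                          processing = processing_config(),
                          digest = digest_config(), seed = 1L) {
  if (noise_ppm < 0) stop("noise_ppm must be >= 0", call. = FALSE)
  if (is.character(planted))
    planted <- data.frame(peptide = planted,
                          parent_protein_id = NA_character_)
  cand <- build_amidation_candidates(proteome, processing, digest)
  windows <- cand$mono_mass
  .with_seed(seed, {
    rows <- list()
    for (s in seq_len(n_replicates)) {
      sid <- sprintf("S%d", s)
      for (i in seq_len(nrow(planted))) {
        theo <- peptide_mass(planted$peptide[i],
                             modifications = "C_TERM_AMIDE", scale = "mono")
        obs <- theo * (1 + stats::runif(1, -noise_ppm, noise_ppm) * 1e-6)
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid,
          peptide_sequence = paste0(planted$peptide[i], "G"),
          observed_neutral_mass = obs,
          parent_protein_id = planted$parent_protein_id[i],
          is_decoy = FALSE)
      }
      d <- 0L; tries <- 0L
      while (d < n_decoys) {
        tries <- tries + 1L
        if (tries > 100L * n_decoys)
          stop("decoy avoidance infeasible: candidate windows too dense",
               call. = FALSE)
        pep <- .random_aa(sample(8:16, 1))
        if (substring(pep, nchar(pep)) == "G") next
        m <- peptide_mass(pep, scale = "mono")
        if (length(windows) > 0L &&
            any(abs(m - windows) / windows * 1e6 < 3 * tol_ppm)) next
        d <- d + 1L
        rows[[length(rows) + 1L]] <- data.frame(
          sample_id = sid, peptide_sequence = pep,
          observed_neutral_mass = m,
          parent_protein_id = sprintf("decoy_parent_%s_%03d", sid, d),
          is_decoy = TRUE)
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    out
  })
}

#' Synthetic spectral-count matrix with replicate dropout
#'
#' Per-protein abundances are log-normal (heavy-tailed, as in label-free
#' spectral-count tables); per-sample counts are Poisson draws around the
#' abundance with a per-observation dropout probability, emulating
#' proteins missing from some replicates.
#'
#' @param n_proteins,n_samples Matrix dimensions.
#' @param meanlog,sdlog Log-normal abundance parameters (defaults 2 and
#'   1.3 give the strong skew typical of ectosome count tables).
#' @param dropout Probability an observation is zeroed (default 0.15).
#' @param seed Random seed.
#' @return Integer detection matrix (proteins x samples).
#' @export
make_count_matrix <- function(n_proteins = 247L, n_samples = 6L,
                              meanlog = 2, sdlog = 1.3, dropout = 0.15,
                              seed = 1L) {
  .with_seed(seed, {
    abundance <- stats::rlnorm(n_proteins, meanlog, sdlog)
    counts <- matrix(stats::rpois(n_proteins * n_samples,
                                  rep(abundance, n_samples)),
                     nrow = n_proteins)
    drop <- matrix(stats::runif(length(counts)) < dropout, nrow = n_proteins)
    counts[drop] <- 0L
    dimnames(counts) <- list(sprintf("prot_%04d", seq_len(n_proteins)),
                             sprintf("S%d", seq_len(n_samples)))
    counts
  })
}

#' One-dimensional diffusion gradient in a closed channel
#'
#' Solves dC/dt = D d2C/dx2 on [0, L] with reflecting (zero-flux) ends and
#' an initial bolus uniform on [0, a] at the chemo-effector end, via the
#' cosine eigenfunction series. Mass is conserved exactly and the profile
#' is monotone non-increasing in x at all times.
#'
#' @param times Times (s) at which to evaluate the profile.
#' @param L Channel length (um; default 50 mm).
#' @param D Diffusion coefficient (um^2/s; default 250, i.e. 2.5e-6
#'   cm^2/s, the Stokes-Einstein scale for a ~2.2-kDa peptide in water;
#'   this regime keeps the profile stable between 1 and 6 hours, as
#'   observed for the fluorescent reporter gradient).
#' @param a Loading segment length (um; default 2500).
#' @param total_mass Total solute mass (arbitrary units).
#' @param nx Number of spatial grid points.
#' @param n_terms Series terms.
#' @return list of class `gradient_profile`: `x` (um), `times` (s),
#'   `conc` (length(x) x length(times) matrix), and the parameters.
#' @export
simulate_gradient <- function(times = c(0, 3600, 21600), L = 5e4, D = 250,
                              a = 2500, total_mass = 1, nx = 201L,
                              n_terms = 400L) {
  if (D <= 0) stop("D must be positive", call. = FALSE)
  if (any(times < 0)) stop("times must be >= 0", call. = FALSE)
  x <- seq(0, L, length.out = nx)
  k <- seq_len(n_terms)
  # series coefficients for a uniform bolus on [0, a]
  coef <- (2 * total_mass / L) * sin(k * pi * a / L) / (k * pi * a / L)
  conc <- vapply(times, function(t) {
    decay <- exp(-D * (k * pi / L)^2 * t)
    total_mass / L + as.vector(cos(outer(x, k * pi / L)) %*% (coef * decay))
  }, numeric(nx))
  conc <- matrix(conc, nrow = nx,
                 dimnames = list(NULL, paste0("t", times)))
  conc[conc < 0] <- 0  # clip series ringing at t ~ 0
  structure(list(x = x, times = times, conc = conc, L = L, D = D, a = a,
                 total_mass = total_mass),
            class = "gradient_profile")
}

#' @export
print.gradient_profile <- function(x, ...) {
  cat(sprintf("<gradient_profile> L=%g um, D=%g um^2/s, %d time point(s)\n",
              x$L, x$D, length(x$times)))
  invisible(x)
}

# |dC/dx| profile at time t (um^-1 scale), from the analytic series
.gradient_slope <- function(gradient, t) {
  k <- seq_len(400L)
  L <- gradient$L
  coef <- (2 * gradient$total_mass / L) *
    sin(k * pi * gradient$a / L) / (k * pi * gradient$a / L)
  decay <- exp(-gradient$D * (k * pi / L)^2 * t)
  x <- gradient$x
  slope <- -as.vector(sin(outer(x, k * pi / L)) %*% (coef * decay * k * pi / L))
  abs(slope)
}

# inverse of the von Mises mean resultant length A(kappa) = I1/I0
.vm_kappa <- function(rho) {
  if (rho <= 0) return(0)
  rho <- min(rho, 0.999)
  stats::uniroot(function(k)
    besselI(k, 1, expon.scaled = TRUE) /
      besselI(k, 0, expon.scaled = TRUE) - rho,
    lower = 1e-8, upper = 2000, tol = 1e-10)$root
}

#' von Mises random angles
#'
#' Best-Fisher rejection sampler, vectorized over observations; `kappa`
#' may be a vector (recycled). `kappa = 0` draws uniform angles.
#'
#' @param n Number of draws.
#' @param mu Mean direction(s), radians.
#' @param kappa Concentration(s), >= 0.
#' @return Angles in (-pi, pi].
#' @export
rvonmises <- function(n, mu = 0, kappa = 1) {
  mu <- rep_len(mu, n)
  kappa <- rep_len(kappa, n)
  out <- numeric(n)
  unif <- kappa < 1e-4   # indistinguishable from uniform; avoids a
  out[unif] <- stats::runif(sum(unif), -pi, pi)  # degenerate envelope
  todo <- which(!unif)
  if (length(todo) > 0L) {
    k <- kappa[todo]
    tau <- 1 + sqrt(1 + 4 * k^2)
    rho <- (tau - sqrt(2 * tau)) / (2 * k)
    r <- (1 + rho^2) / (2 * rho)
    theta <- rep(NA_real_, length(todo))
    pending <- seq_along(todo)
    while (length(pending) > 0L) {
      u1 <- stats::runif(length(pending))
      u2 <- stats::runif(length(pending))
      z <- cos(pi * u1)
      f <- pmin(pmax((1 + r[pending] * z) / (r[pending] + z), -1), 1)
      c_ <- k[pending] * (r[pending] - f)
      ok <- (c_ * (2 - c_) - u2 > 0) |
        (c_ > 0 & log(c_ / u2) + 1 - c_ >= 0)
      ok[is.na(ok)] <- FALSE
      if (any(ok)) {
        u3 <- stats::runif(sum(ok))
        theta[pending[ok]] <- sign(u3 - 0.5) * acos(f[ok])
      }
      pending <- pending[!ok]
    }
    out[todo] <- theta
  }
  ang <- out + mu
  # wrap to (-pi, pi]
  ang <- ang - 2 * pi * floor((ang + pi) / (2 * pi))
  ang
}

#' Walk parameters for the gamete swimming simulator
#'
#' @param n_cells Number of cells.
#' @param speed_range Per-cell speed band in um/s (default 100-150, the
#'   reported gamete swimming speed).
#' @param dt Step interval (s; default 0.5, the tracking interval).
#' @param duration Track duration (s; default 10, the tracking protocol).
#' @param lambda Chemotactic bias in [-1, 1]: the mean cosine of step
#'   directions relative to the up-gradient axis (negative = repulsion).
#' @param seed Random seed.
#' @export
walk_params <- function(n_cells = 200L, speed_range = c(100, 150),
                        dt = 0.5, duration = 10, lambda = 0, seed = 1L) {
  if (abs(lambda) > 1) stop("|lambda| must be <= 1", call. = FALSE)
  if (any(speed_range <= 0) || dt <= 0 || duration <= 0)
    stop("speeds, dt and duration must be positive", call. = FALSE)
  list(n_cells = as.integer(n_cells), speed_range = speed_range, dt = dt,
       duration = duration, lambda = lambda, seed = seed)
}

# core step engine; channel = c(L, W) um, chemo-effector end at x = 0.
# Returns positions at every step (n_cells x n_steps+1 matrices).
.simulate_walk <- function(params, gradient = NULL, gradient_time = 3600,
                           start = NULL) {
  n <- params$n_cells
  n_steps <- ceiling(params$duration / params$dt)
  L <- 5e4; W <- 5e3
  if (!is.null(gradient)) L <- gradient$L
  speed <- stats::runif(n, params$speed_range[1L], params$speed_range[2L])
  if (is.null(start)) {
    x <- stats::runif(n, 0, L)
    y <- stats::runif(n, 0, W)
  } else {
    x <- rep_len(start[[1L]], n); y <- rep_len(start[[2L]], n)
  }
  lambda <- params$lambda
  mu <- if (lambda >= 0) pi else 0   # up-gradient = toward x = 0
  slope_fun <- NULL
  if (!is.null(gradient)) {
    s <- .gradient_slope(gradient, gradient_time)
    smax <- max(s)
    if (smax > 0)
      slope_fun <- stats::approxfun(gradient$x, s / smax, rule = 2)
  }
  kappa_base <- .vm_kappa(abs(lambda))
  X <- matrix(NA_real_, n, n_steps + 1L)
  Y <- matrix(NA_real_, n, n_steps + 1L)
  X[, 1L] <- x; Y[, 1L] <- y
  # precompute kappa over a grid of local bias values for the scaled case
  kappa_of <- NULL
  if (!is.null(slope_fun) && abs(lambda) > 0) {
    grid <- seq(0, abs(lambda), length.out = 64L)
    kgrid <- vapply(grid, .vm_kappa, numeric(1))
    kappa_of <- stats::approxfun(grid, kgrid, rule = 2)
  }
  for (s_i in seq_len(n_steps)) {
    if (is.null(slope_fun) || abs(lambda) == 0) {
      kap <- kappa_base
    } else {
      kap <- kappa_of(abs(lambda) * slope_fun(x))
    }
    theta <- rvonmises(n, mu = mu, kappa = kap)
    x <- x + speed * params$dt * cos(theta)
    y <- y + speed * params$dt * sin(theta)
    # reflecting walls
    x <- abs(x); x <- L - abs(L - x)
    y <- abs(y); y <- W - abs(W - y)
    X[, s_i + 1L] <- x
    Y[, s_i + 1L] <- y
  }
  list(X = X, Y = Y, speed = speed, dt = params$dt, L = L, W = W)
}

#' Simulate gamete trajectories as a biased random walk
#'
#' Each cell swims at a constant speed drawn from `speed_range`; at every
#' step its heading is drawn from a von Mises distribution centered on the
#' up-gradient axis (toward the chemo-effector at x = 0; centered
#' down-gradient for negative bias) with concentration chosen so the mean
#' heading cosine equals `lambda`. Speed is independent of the bias by
#' construction, matching the observation that the amidated peptide
#' changes direction, not swimming velocity. When a `gradient` is
#' supplied, the effective bias of each cell is scaled by the local
#' normalized gradient slope, so cells outside the gradient front swim
#' unbiased. Positions are confined to the 50 x 5 mm channel by
#' reflection.
#'
#' @param params A [walk_params()].
#' @param gradient Optional [simulate_gradient()] output; `NULL` applies
#'   the full bias everywhere (uniform-gradient idealization).
#' @param gradient_time Time (s) at which the gradient is sensed.
#' @return data.frame with columns `cell`, `t`, `x`, `y`.
#' @export
simulate_trajectories <- function(params = walk_params(), gradient = NULL,
                                  gradient_time = 3600) {
  .with_seed(params$seed, {
    w <- .simulate_walk(params, gradient, gradient_time)
    n_steps <- ncol(w$X) - 1L
    data.frame(
      cell = rep(seq_len(params$n_cells), each = n_steps + 1L),
      t = rep(seq(0, by = params$dt, length.out = n_steps + 1L),
              params$n_cells),
      x = as.vector(t(w$X)),
      y = as.vector(t(w$Y)))
  })
}

#' Estimate the chemotactic bias from tracks
#'
#' The bias lambda is the mean cosine of step headings relative to the
#' up-gradient axis (toward x = 0); this estimator inverts the simulator's
#' definition directly.
#'
#' @param trajectories Output of [simulate_trajectories()].
#' @return Estimated lambda.
#' @export
estimate_bias <- function(trajectories) {
  g <- trajectories[order(trajectories$cell, trajectories$t), ]
  dx <- diff(g$x); dy <- diff(g$y)
  same <- diff(g$cell) == 0
  dx <- dx[same]; dy <- dy[same]
  len <- sqrt(dx^2 + dy^2)
  ok <- len > 0
  mean(-dx[ok] / len[ok])
}

#' Simulate region occupancy counts over hours
#'
#' Runs the biased walk at a coarse step (`dt`, default 5 s — the regional
#' redistribution is hour-scale, so sub-second stepping is unnecessary)
#' from a uniform initial distribution, and tallies cells in the three
#' equal channel thirds at each requested hour. Region 2 is the third
#' nearest the chemo-effector (x = 0), region 0 nearest the cell
#' reservoir.
#'
#' @param params A [walk_params()] (its `duration` is ignored; `dt` may be
#'   overridden via `dt`).
#' @param gradient Optional gradient (bias scaled by the local slope,
#'   sensed at the median requested time).
#' @param times_h Hours at which to count (default 1:4).
#' @param dt Coarse step interval in seconds (default 5).
#' @param region_fractions Channel fractions of regions 2, 1, 0 (default
#'   equal thirds).
#' @return data.frame: `time_h`, `n0`, `n1`, `n2`.
#' @export
simulate_region_counts <- function(params = walk_params(n_cells = 1000L),
                                   gradient = NULL, times_h = 1:4, dt = 5,
                                   region_fractions = rep(1 / 3, 3)) {
  stopifnot(all(times_h > 0), abs(sum(region_fractions) - 1) < 1e-9)
  .with_seed(params$seed, {
    p <- params
    p$dt <- dt
    p$duration <- max(times_h) * 3600
    w <- .simulate_walk(p, gradient,
                        gradient_time = stats::median(times_h) * 3600)
    b2 <- w$L * region_fractions[1L]
    b1 <- w$L * (region_fractions[1L] + region_fractions[2L])
    out <- lapply(times_h, function(h) {
      col <- min(ncol(w$X), round(h * 3600 / dt) + 1L)
      x <- w$X[, col]
      data.frame(time_h = h,
                 n0 = sum(x >= b1),
                 n1 = sum(x >= b2 & x < b1),
                 n2 = sum(x < b2))
    })
    do.call(rbind, out)
  })
}
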