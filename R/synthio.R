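# run code under a local, seeded RNG stream without disturbing the caller's
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' Configure a synthetic TMA world
#'
#' The generator emulates the structure of a prostatectomy TMA biobank:
#' per-TMA blocks of cases, a latent per-case risk driving both survival
#' and planted image morphology, per-TMA staining bias, right-censored
#' follow-up, and a tunable rate of "unrepresentative" spots whose tissue
#' was sampled at a location that does not reflect the case's risk.
#'
#' @param n_tmas Number of TMA blocks.
#' @param cases_per_tma Cases per TMA (one spot per case).
#' @param spot_px Spot image side length in pixels (default 192).
#' @param morphology_effect Effect size linking latent risk to the planted
#'   blob texture; 0 plants no signal, 1 spans the full blob-density range.
#' @param tma_stain_shift Half-range of the per-TMA additive channel bias
#'   (0 disables the staining confound).
#' @param stain_follows_risk If `TRUE` the TMA staining/thickness biases
#'   are correlated with the TMA's risk mix (the shortcut TMA-balancing
#'   must defeat).
#' @param tma_artifact Mean count of pale tear-like section artifacts per
#'   spot, a thickness-style texture bias that survives per-spot OD
#'   normalization (unlike the channel stain shift). 0 disables; with
#'   `stain_follows_risk` the per-TMA artifact rate scales with the TMA's
#'   risk mix.
#' @param tma_thickness Half-range of the per-TMA section-thickness noise
#'   multiplier (0 disables): thicker sections render with grainier
#'   tissue texture in every patch, a dense TMA signature that survives
#'   OD normalization. With `stain_follows_risk` the multiplier tracks
#'   the TMA's risk mix.
#' @param tma_hue Half-range of the per-TMA hue rotation (fraction of a
#'   full rotation; 0 disables). A hue rotation mixes channels, so unlike
#'   an additive stain shift it survives per-channel OD standardization —
#'   the trivially separable stain fingerprint a TMA-overfitting model
#'   latches onto. With `stain_follows_risk` it tracks the risk mix.
#' @param tma_risk_spread Spread of per-TMA mean latent risk in \[0, 0.5);
#'   0 makes every TMA share the same risk mix.
#' @param unrepresentative_rate Probability that a spot is rendered from
#'   the opposite latent (`1 - latent`) while keeping the case's label.
#' @param prevalence Target bad-outcome fraction (paper-calibrated default
#'   0.237).
#' @param beta_hazard Log hazard ratio per unit of latent risk in the
#'   exponential survival model (default 5, giving a near-deterministic
#'   link between latent risk and outcome so the planted morphology is
#'   learnable in principle).
#' @param latent_conc Beta concentration of the per-case latent risk
#'   around the TMA mean; values below 1 give a bimodal (clearly high vs
#'   clearly low) population (default 0.8).
#' @param censor_max Censoring/follow-up horizon: censoring times are
#'   Uniform(0, `censor_max`) years (default 10).
#' @param seed Integer; fully determines the world.
#' @return A `world_config` list.
#' @export
world_config <- function(n_tmas = 8, cases_per_tma = 25, spot_px = 192,
                         morphology_effect = 1.0, tma_stain_shift = 0,
                         stain_follows_risk = FALSE, tma_artifact = 0,
                         tma_thickness = 0, tma_hue = 0, tma_risk_spread = 0,
                         unrepresentative_rate = 0, prevalence = 0.237,
                         beta_hazard = 5, latent_conc = 0.8,
                         censor_max = 10, seed = 1) {
  stopifnot(prevalence > 0, prevalence < 1,
            unrepresentative_rate >= 0, unrepresentative_rate <= 1,
            tma_risk_spread >= 0, tma_risk_spread < 0.5,
            morphology_effect >= 0, censor_max > 0)
  structure(as.list(environment()), class = "world_config")
}

#' Canonical confounded world for the sampling-strategy ablation
#'
#' A world whose TMAs differ strongly in outcome mix (`tma_risk_spread
#' 0.45`) while each TMA carries a random handling signature (a stain hue
#' fingerprint, fold artifacts, section-thickness noise) unrelated to
#' risk. A fifth of spots are unrepresentative
#' (`unrepresentative_rate 0.2`): their image contradicts the case label,
#' which caps how well genuine morphology can explain the training labels
#' while leaving the TMA fingerprint's majority-label shortcut untouched.
#' Memorizing a TMA's signature then competes with morphology in
#' training, but on held-out TMA blocks the memorized signatures are
#' absent, so only morphology (`morphology_effect 0.5`) transfers. This
#' is the regime in which TMA-balanced drafting and label curation are
#' expected to help.
#'
#' @param seed Integer; fully determines the world.
#' @param ... Overrides forwarded to [world_config()].
#' @return A `world_config` list.
#' @export
confounded_world_config <- function(seed = 1, ...) {
  defaults <- list(
    n_tmas = 10, cases_per_tma = 30, spot_px = 192,
    morphology_effect = 0.5, tma_risk_spread = 0.45,
    tma_artifact = 10, tma_thickness = 0.6, tma_hue = 0.08,
    unrepresentative_rate = 0.2,
    seed = seed
  )
  over <- list(...)
  do.call(world_config, utils::modifyList(defaults, over))
}

# P(event observed) for one case: T ~ Exp(rate), C ~ Unif(0, cmax)
p_event_given_rate <- function(rate, cmax) {
  1 - (1 - exp(-rate * cmax)) / (rate * cmax)
}

# solve the baseline hazard so that the mean event probability over the
# drawn latents hits the target prevalence
calibrate_base_rate <- function(latents, beta, cmax, prevalence) {
  f <- function(log_l0) {
    mean(p_event_given_rate(exp(log_l0 + beta * latents), cmax)) - prevalence
  }
  lo <- -12; hi <- 8
  if (f(lo) > 0 || f(hi) < 0) {
    stop(sprintf(
      "target prevalence %.3f unreachable: achievable range is [%.4f, %.4f] given censor_max %.1f",
      prevalence, mean(p_event_given_rate(exp(lo + beta * latents), cmax)) + prevalence - prevalence,
      mean(p_event_given_rate(exp(hi + beta * latents), cmax)), cmax))
  }
  exp(stats::uniroot(f, c(lo, hi), tol = 1e-10)$root)
}

#' Generate the synthetic cohort (cases, outcomes, follow-up)
#'
#' Draws a latent risk per case (Beta-distributed around a per-TMA mean),
#' event times from an exponential hazard `base_rate * exp(beta * latent)`,
#' uniform censoring, and clinical covariates. The event observed before
#' censoring becomes a bad-outcome event (BCR, metastasis or
#' cancer-specific death, with BCR dominating as in real cohorts);
#' follow-up runs to the censoring time. Ground-truth latents are returned
#' separately from the cohort table and must never feed training code.
#'
#' @param config A [world_config()].
#' @return A list: `cohort` (canonical cohort tibble), `truth` (tibble
#'   `case_id`, `tma_id`, `latent`), `tma_profiles` (tibble `tma_id`,
#'   `risk_mix`, `stain_r`, `stain_g`, `stain_b`), `base_rate`.
#' @export
generate_cohort <- function(config) {
  with_seed(config$seed, {
    n <- config$n_tmas * config$cases_per_tma
    tma_ids <- sprintf("tma%02d", seq_len(config$n_tmas))

    mix <- 0.5 + config$tma_risk_spread *
      seq(-1, 1, length.out = config$n_tmas)
    stain <- matrix(0, config$n_tmas, 3)
    if (config$tma_stain_shift > 0) {
      if (config$stain_follows_risk) {
        # bias tracks the TMA's risk mix, plus a little noise
        base <- (mix - 0.5) / max(config$tma_risk_spread, 0.25)
        stain[, 1] <- config$tma_stain_shift * (base + stats::rnorm(config$n_tmas, 0, 0.2))
        stain[, 2] <- -config$tma_stain_shift * (base + stats::rnorm(config$n_tmas, 0, 0.2))
        stain[, 3] <- config$tma_stain_shift * stats::rnorm(config$n_tmas, 0, 0.5)
      } else {
        stain[] <- stats::runif(config$n_tmas * 3, -config$tma_stain_shift,
                                config$tma_stain_shift)
      }
    }
    artifact_rate <- if (config$tma_artifact > 0 && config$stain_follows_risk) {
      config$tma_artifact * (0.2 + 1.6 * mix)
    } else if (config$tma_artifact > 0) {
      # random per-TMA handling signature, uncorrelated with risk
      config$tma_artifact * stats::runif(config$n_tmas, 0.2, 1.8)
    } else {
      rep(0, config$n_tmas)
    }
    hue_shift <- if (config$tma_hue > 0) {
      if (config$stain_follows_risk) {
        config$tma_hue * (2 * mix - 1)
      } else {
        stats::runif(config$n_tmas, -config$tma_hue, config$tma_hue)
      }
    } else {
      rep(0, config$n_tmas)
    }
    noise_mult <- if (config$tma_thickness > 0) {
      if (config$stain_follows_risk) {
        1 + config$tma_thickness * (2 * mix - 1)
      } else {
        1 + stats::runif(config$n_tmas, -config$tma_thickness, config$tma_thickness)
      }
    } else {
      rep(1, config$n_tmas)
    }
    tma_profiles <- tibble::tibble(
      tma_id = tma_ids, risk_mix = mix,
      stain_r = stain[, 1], stain_g = stain[, 2], stain_b = stain[, 3],
      artifact_rate = artifact_rate, noise_mult = noise_mult,
      hue_shift = hue_shift
    )

    case_tma <- rep(tma_ids, each = config$cases_per_tma)
    conc <- config$latent_conc
    m <- rep(mix, each = config$cases_per_tma)
    latent <- stats::rbeta(n, m * conc, (1 - m) * conc)

    base_rate <- calibrate_base_rate(latent, config$beta_hazard,
                                     config$censor_max, config$prevalence)
    rate <- base_rate * exp(config$beta_hazard * latent)
    t_event <- stats::rexp(n, rate)
    c_time <- stats::runif(n, 0, config$censor_max)
    event <- t_event <= c_time

    # one event type per event, BCR-dominated
    type <- sample(c("bcr", "met", "cdeath"), n, replace = TRUE,
                   prob = c(0.8, 0.15, 0.05))
    flag <- function(kind) event & type == kind
    tm <- function(kind) ifelse(flag(kind), round(t_event, 4), NA_real_)

    # spread flags rise steeply with latent risk; each independently missing 20%
    p_spread <- stats::plogis(-5 + 7 * latent)
    mk_flag <- function() {
      f <- stats::runif(n) < p_spread
      f[stats::runif(n) < 0.2] <- NA
      f
    }

    cohort <- tibble::tibble(
      case_id = sprintf("case%04d", seq_len(n)),
      tma_id = case_tma,
      age = round(stats::rnorm(n, 64, 7), 1),
      psa = round(stats::rlnorm(n, log(7), 0.6), 2),
      isup = pmin(5, 1 + stats::rbinom(n, 4, latent)),
      pt = pmin(4, 2 + stats::rbinom(n, 2, latent)),
      pn = mk_flag(), pv = mk_flag(), pl = mk_flag(),
      fu_years = round(c_time, 4),
      bcr = flag("bcr"), t_bcr = tm("bcr"),
      met = flag("met"), t_met = tm("met"),
      cdeath = flag("cdeath"), t_cdeath = tm("cdeath")
    )
    truth <- tibble::tibble(case_id = cohort$case_id, tma_id = case_tma,
                            latent = latent)
    list(cohort = cohort, truth = truth, tma_profiles = tma_profiles,
         base_rate = base_rate)
  })
}

#' Render one synthetic TMA spot image
#'
#' A roughly circular eosin-pink tissue disc on a light background, with
#' dark nuclei-like blobs whose density increases with the latent risk
#' (slope set by `morphology_effect`), the TMA's staining bias added to
#' the tissue channels, and mild pixel noise. Bit-identical for a fixed
#' seed.
#'
#' @param latent Latent risk in \[0, 1\] driving the blob texture.
#' @param tma One row of the `tma_profiles` tibble (or a list with
#'   `stain_r`, `stain_g`, `stain_b`), or `NULL` for no bias.
#' @param spot_px Image side length.
#' @param morphology_effect Texture-vs-risk slope (see [world_config()]).
#' @param seed Integer seed for this spot.
#' @return A spot_px x spot_px x 3 linear RGB array in \[0, 1\].
#' @export
render_spot <- function(latent, tma = NULL, spot_px = 192,
                        morphology_effect = 1.0, seed = 1) {
  if (latent < 0 || latent > 1) stop("latent must lie in [0, 1]")
  with_seed(seed, {
    p <- spot_px
    img <- array(stats::rnorm(p * p * 3, 0.94, 0.01), dim = c(p, p, 3))

    cx <- (p + 1) / 2
    dist2 <- outer((seq_len(p) - cx)^2, (seq_len(p) - cx)^2, "+")
    disc <- dist2 <= (0.45 * p)^2

    nm <- if (!is.null(tma) && !is.null(tma$noise_mult)) tma$noise_mult else 1

    base <- c(0.85, 0.62, 0.78)  # eosin-pink tissue
    for (ch in 1:3) {
      layer <- img[, , ch]
      layer[disc] <- base[ch] + stats::rnorm(sum(disc), 0, 0.03 * nm)
      img[, , ch] <- layer
    }

    # planted morphology: dark nuclei-like blobs, density monotone in latent
    area_scale <- (p / 192)^2
    n0 <- round(60 * area_scale)
    n_blobs <- round(n0 * (1 + morphology_effect * (2 * latent - 1)))
    n_blobs <- max(0L, n_blobs)
    nucleus <- c(0.32, 0.22, 0.52)  # hematoxylin-dark purple
    if (n_blobs > 0) {
      r_disc <- 0.45 * p
      theta <- stats::runif(n_blobs, 0, 2 * pi)
      rad <- r_disc * sqrt(stats::runif(n_blobs)) * 0.95
      bx <- round(cx + rad * cos(theta))
      by <- round(cx + rad * sin(theta))
      br <- stats::runif(n_blobs, 1.5, 3.5)
      for (i in seq_len(n_blobs)) {
        w <- ceiling(br[i])
        rows <- max(1, bx[i] - w):min(p, bx[i] + w)
        cols <- max(1, by[i] - w):min(p, by[i] + w)
        d2 <- outer((rows - bx[i])^2, (cols - by[i])^2, "+")
        inside <- d2 <= br[i]^2
        for (ch in 1:3) {
          block <- img[rows, cols, ch]
          block[inside] <- nucleus[ch] + stats::rnorm(sum(inside), 0, 0.02 * nm)
          img[rows, cols, ch] <- block
        }
      }
    }

    if (!is.null(tma)) {
      # pale tear-like section artifacts: texture-level TMA bias that
      # survives per-spot, per-channel OD standardization
      a_rate <- if (!is.null(tma$artifact_rate)) tma$artifact_rate else 0
      if (a_rate > 0) {
        n_art <- stats::rpois(1, a_rate * area_scale)
        if (n_art > 0) {
          r_disc <- 0.45 * p
          theta <- stats::runif(n_art, 0, 2 * pi)
          rad <- r_disc * sqrt(stats::runif(n_art)) * 0.85
          ax <- round(cx + rad * cos(theta))
          ay <- round(cx + rad * sin(theta))
          ar <- stats::runif(n_art, 3, 7)
          for (i in seq_len(n_art)) {
            w <- ceiling(ar[i])
            rows <- max(1, ax[i] - w):min(p, ax[i] + w)
            cols <- max(1, ay[i] - w):min(p, ay[i] + w)
            d2 <- outer((rows - ax[i])^2, (cols - ay[i])^2, "+")
            inside <- d2 <= ar[i]^2
            fold <- c(0.72, 0.78, 0.90)  # blue-grey fold/blur artifact
            for (ch in 1:3) {
              block <- img[rows, cols, ch]
              block[inside] <- fold[ch] + stats::rnorm(sum(inside), 0, 0.01)
              img[rows, cols, ch] <- block
            }
          }
        }
      }
      gv <- function(x) if (is.null(x)) 0 else x
      shift <- c(gv(tma$stain_r), gv(tma$stain_g), gv(tma$stain_b))
      if (any(shift != 0)) {
        for (ch in 1:3) {
          layer <- img[, , ch]
          layer[disc] <- layer[disc] + shift[ch]
          img[, , ch] <- layer
        }
      }
      # hue rotation: a channel-mixing stain fingerprint that per-channel
      # OD standardization cannot undo (greys are hue-invariant)
      if (gv(tma$hue_shift) != 0) {
        img <- rotate_hue(pmin(pmax(img, 0), 1), tma$hue_shift)
      }
    }
    pmin(pmax(img, 0), 1)
  })
}

#' Planted texture statistic of a spot
#'
#' The independently measurable statistic the renderer plants: the
#' fraction of tissue pixels that are nuclei-dark (mean optical density
#' above `dark_od`). Monotone in the latent risk used to render the spot,
#' which makes it a direct oracle for what the MIL model can learn.
#'
#' @param image HxWx3 linear RGB array.
#' @param dark_od Mean-OD threshold separating nuclei-dark pixels from
#'   plain tissue (default 0.6).
#' @return Fraction in \[0, 1\] (relative to tissue pixels).
#' @export
planted_stat <- function(image, dark_od = 0.6) {
  od <- od_transform(image)
  mean_od <- (od[, , 1] + od[, , 2] + od[, , 3]) / 3
  tissue <- mean_od > 0.15
  if (!any(tissue)) return(0)
  mean(mean_od[tissue] > dark_od)
}

#' Simulate a complete synthetic TMA world
#'
#' Generates the cohort via [generate_cohort()] and renders one spot per
#' case via [render_spot()]. With probability `unrepresentative_rate` a
#' spot's texture is rendered from the opposite latent (`1 - latent`)
#' while the case keeps its outcome-derived label — the mechanism the
#' denoising stage must detect. The whole world is a pure function of the
#' config (seed included).
#'
#' @param config A [world_config()].
#' @return A `tma_world` list: `cohort`, `truth` (with `latent_render` and
#'   `unrepresentative` columns added), `tma_profiles`, `spots` (manifest
#'   tibble: `spot_id`, `case_id`, `tma_id`), `images` (named list of
#'   arrays keyed by `spot_id`), `base_rate`, `config`.
#' @export
simulate_world <- function(config) {
  gen <- generate_cohort(config)
  n <- nrow(gen$cohort)
  extras <- with_seed(config$seed + 1L, {
    list(unrep = stats::runif(n) < config$unrepresentative_rate,
         spot_seeds = sample.int(.Machine$integer.max - 1L, n))
  })
  truth <- gen$truth
  truth$unrepresentative <- extras$unrep
  truth$latent_render <- ifelse(extras$unrep, 1 - truth$latent, truth$latent)

  profiles <- split(gen$tma_profiles, gen$tma_profiles$tma_id)
  images <- vector("list", n)
  spot_ids <- sprintf("spot%04d", seq_len(n))
  for (i in seq_len(n)) {
    images[[i]] <- render_spot(
      latent = truth$latent_render[i],
      tma = profiles[[gen$cohort$tma_id[i]]],
      spot_px = config$spot_px,
      morphology_effect = config$morphology_effect,
      seed = extras$spot_seeds[i]
    )
  }
  names(images) <- spot_ids
  structure(list(
    cohort = gen$cohort, truth = truth, tma_profiles = gen$tma_profiles,
    spots = tibble::tibble(spot_id = spot_ids, case_id = gen$cohort$case_id,
                           tma_id = gen$cohort$tma_id),
    images = images, base_rate = gen$base_rate, config = config
  ), class = "tma_world")
}

#' @export
print.tma_world <- function(x, ...) {
  cat(sprintf(
    "<tma_world> %d cases on %d TMAs, %d spots of %d px; bad-outcome fraction %.3f\n",
    nrow(x$cohort), x$config$n_tmas, length(x$images), x$config$spot_px,
    mean(derive_bad_outcome(x$cohort)$bad_outcome)))
  invisible(x)
}

#' Write a synthetic world to disk
#'
#' Writes the cohort table (TSV), spot manifest (TSV), spot images (PNG),
#' and the ground-truth manifest (JSON; latents, unrepresentative flags,
#' TMA profiles, baseline hazard). The ground-truth file exists for test
#' assertions only and is never read by training code.
#'
#' @param world A `tma_world`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(file.path(dir, "spots"), recursive = TRUE, showWarnings = FALSE)
  write_cohort(world$cohort, file.path(dir, "cohort.tsv"))
  manifest <- world$spots
  manifest$image_path <- file.path("spots", paste0(manifest$spot_id, ".png"))
  readr::write_tsv(manifest, file.path(dir, "spot_manifest.tsv"))
  for (i in seq_len(nrow(manifest))) {
    png::writePNG(world$images[[manifest$spot_id[i]]],
                  file.path(dir, manifest$image_path[i]))
  }
  jsonlite::write_json(
    list(truth = world$truth, tma_profiles = world$tma_profiles,
         base_rate = world$base_rate,
         config = world$config[setdiff(names(world$config), "")]),
    file.path(dir, "world_truth.json"),
    dataframe = "columns", auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Read a spot image from disk
#'
#' @param path A PNG file.
#' @return HxWx3 linear RGB array in \[0, 1\].
#' @export
read_spot <- function(path) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), dim = c(dim(img), 3))
  img[, , 1:3, drop = FALSE]
}
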