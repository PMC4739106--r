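#' Synthetic study configuration
#'
#' Bundles every generative parameter of the synthetic-data module. Defaults
#' emulate the study design: two reference regions diverged at F_ST of about
#' 0.004, twelve microsatellite loci of fifteen alleles with uneven
#' (broken-stick) ancestral frequencies, reference sample sizes 435
#' (Kattegat) and 201 (North Sea/W Skagerrak), a tagged cohort of 100 fish
#' released in the eastern Skagerrak and Kattegat of which about 35 per cent
#' are directional migrants, strong philopatry, and noisy daily-longitude
#' tracks with occasional single-day outliers.
#'
#' @param n_pops Number of reference populations (>= 2).
#' @param fst Divergence target F in (0, 1) of the Balding-Nichols model.
#' @param n_loci Number of loci.
#' @param alleles_per_locus Scalar or per-locus vector of allele counts
#'   (each >= 2).
#' @param ancestral `"broken_stick"` (uneven, realistic) or `"uniform"`
#'   (equal frequencies).
#' @param sample_sizes Per-population reference sample sizes; named by
#'   population or positional.
#' @param pop_names Population (pool) names; first name is the
#'   tie-break/first-listed pool.
#' @param missing_rate Per-call missing-data probability in \[0, 0.5\].
#' @param n_tagged Tagged-cohort size.
#' @param origin_mix Origin-pool probabilities for tagged fish (sums to 1).
#' @param philopatry_prob Probability a directional migrant heads toward its
#'   origin region (phi).
#' @param p_migratory Probability a tagged fish is a directional migrant.
#' @param release_mix Release-region probabilities
#'   (`ESkagerrak`, `Kattegat`).
#' @param track_noise_sd Daily-longitude Gaussian noise, degrees.
#' @param outlier_rate Single-day outlier probability in \[0, 0.2\] (outliers
#'   are isolated: never two consecutive days).
#' @param behaviour_counts Optional named vector of the five behaviour-group
#'   sizes (must sum to `n_tagged`); overrides `p_migratory`/`release_mix`
#'   to reproduce a fixed group design.
#' @param seed Integer root seed; every output is bit-reproducible given it.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pops = 2, fst = 0.004, n_loci = 12, alleles_per_locus = 15,
                       ancestral = c("broken_stick", "uniform"),
                       sample_sizes = c(435, 201),
                       pop_names = c("Kattegat", "NorthSea_WSkagerrak"),
                       missing_rate = 0.02, n_tagged = 100,
                       origin_mix = c(0.5, 0.5), philopatry_prob = 0.9,
                       p_migratory = 0.35,
                       release_mix = c(ESkagerrak = 0.59, Kattegat = 0.41),
                       track_noise_sd = 0.2, outlier_rate = 0.05,
                       behaviour_counts = NULL, seed = 1) {
  ancestral <- match.arg(ancestral)
  if (n_pops < 2) abort("`n_pops` must be at least 2.")
  if (fst <= 0 || fst >= 1) abort("`fst` must lie in (0, 1).")
  if (any(alleles_per_locus < 2)) abort("`alleles_per_locus` must be at least 2.")
  if (missing_rate < 0 || missing_rate > 0.5) abort("`missing_rate` must lie in [0, 0.5].")
  if (outlier_rate < 0 || outlier_rate > 0.2) abort("`outlier_rate` must lie in [0, 0.2].")
  if (abs(sum(origin_mix) - 1) > 1e-8) abort("`origin_mix` must sum to 1.")
  if (abs(sum(release_mix) - 1) > 1e-8) abort("`release_mix` must sum to 1.")
  if (length(pop_names) != n_pops) abort("`pop_names` must have `n_pops` entries.")
  if (length(sample_sizes) != n_pops) abort("`sample_sizes` must have `n_pops` entries.")
  if (any(sample_sizes < 1) || n_tagged < 1) abort("All counts must be >= 1.")
  if (!is.null(behaviour_counts)) {
    groups <- c("SkagerrakToNorthSea", "KattegatToNorthSea", "SkagerrakToKattegat",
                "NonmigratorySkagerrak", "NonmigratoryKattegat")
    if (!setequal(names(behaviour_counts), groups) || sum(behaviour_counts) != n_tagged) {
      abort("`behaviour_counts` must name the five behaviour groups and sum to `n_tagged`.")
    }
  }
  alleles_per_locus <- rep_len(alleles_per_locus, n_loci)
  structure(
    list(n_pops = n_pops, fst = fst, n_loci = n_loci,
         alleles_per_locus = alleles_per_locus, ancestral = ancestral,
         sample_sizes = setNames(sample_sizes, pop_names), pop_names = pop_names,
         missing_rate = missing_rate, n_tagged = n_tagged,
         origin_mix = setNames(rep_len(origin_mix, n_pops), pop_names),
         philopatry_prob = philopatry_prob, p_migratory = p_migratory,
         release_mix = release_mix, track_noise_sd = track_noise_sd,
         outlier_rate = outlier_rate, behaviour_counts = behaviour_counts,
         seed = as.integer(seed)),
    class = "sim_config"
  )
}

locus_names <- function(n_loci) sprintf("loc%02d", seq_len(n_loci))

#' Simulate population allele frequencies (Balding-Nichols model)
#'
#' Ancestral frequencies per locus come from the chosen model; each
#' population's frequencies are then drawn from a Dirichlet with parameters
#' `p0 (1 - F) / F`, independently per population and locus, so the expected
#' Weir-Cockerham theta between populations is approximately `F`.
#'
#' @param config A [sim_config()].
#' @param seed Optional seed override (default: the config seed).
#' @return A tibble: `pop`, `locus`, `allele`, `freq`, with the ancestral
#'   frequencies attached as attribute `ancestral` (tibble `locus`,
#'   `allele`, `freq`).
#' @export
sim_allele_freqs <- function(config, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  loci <- locus_names(config$n_loci)
  with_seed(derive_seed(seed, "allele-freqs"), {
    anc <- lapply(seq_len(config$n_loci), function(i) {
      k <- config$alleles_per_locus[i]
      p0 <- if (config$ancestral == "uniform") {
        rep(1 / k, k)
      } else {
        p <- rdirichlet1(rep(1, k))
        p <- pmax(p, 0.005)
        p / sum(p)
      }
      tibble(locus = loci[i], allele = seq_len(k), freq = p0)
    })
    anc <- dplyr::bind_rows(anc)
    pops <- lapply(config$pop_names, function(q) {
      per_locus <- lapply(split(anc, anc$locus)[loci], function(d) {
        f <- rdirichlet1(d$freq * (1 - config$fst) / config$fst)
        tibble(pop = q, locus = d$locus, allele = d$allele, freq = f)
      })
      dplyr::bind_rows(per_locus)
    })
    out <- dplyr::bind_rows(pops)
    attr(out, "ancestral") <- anc
    out
  })
}

#' Simulate HWE genotypes from allele frequencies
#'
#' Each individual draws two alleles per locus independently
#' (Hardy-Weinberg); each locus call is then erased with probability
#' `missing_rate`.
#'
#' @param freqs Frequency tibble (`locus`, `allele`, `freq`), e.g. one
#'   population's rows from [sim_allele_freqs()].
#' @param n Number of individuals.
#' @param missing_rate Per-call erasure probability.
#' @param seed Integer seed.
#' @param label Sample label (also the individual-id prefix).
#' @param cohorts Optional vector of cohort labels sampled uniformly per
#'   individual (adds a `cohort` column).
#' @return A genotype table.
#' @export
sim_genotypes <- function(freqs, n, missing_rate = 0, seed = 1, label = "sim",
                          cohorts = NULL) {
  if ("pop" %in% names(freqs) && length(unique(freqs$pop)) > 1) {
    abort("`freqs` holds several populations; filter to one before simulating.")
  }
  loci <- unique(freqs$locus)
  with_seed(derive_seed(seed, paste0("genotypes-", label)), {
    per_locus <- lapply(loci, function(l) {
      d <- freqs[freqs$locus == l, ]
      a1 <- d$allele[sample.int(nrow(d), n, replace = TRUE, prob = d$freq)]
      a2 <- d$allele[sample.int(nrow(d), n, replace = TRUE, prob = d$freq)]
      miss <- runif(n) < missing_rate
      a1[miss] <- NA_integer_
      a2[miss] <- NA_integer_
      tibble(sample = label,
             individual_id = sprintf("%s_%04d", label, seq_len(n)),
             locus = l, allele_1 = as.integer(a1), allele_2 = as.integer(a2))
    })
    out <- dplyr::bind_rows(per_locus)
    out <- as_geno_tbl(out, loci = loci, samples = label)
    if (!is.null(cohorts)) {
      coh <- setNames(sample(as.character(cohorts), n, replace = TRUE),
                      sprintf("%s_%04d", label, seq_len(n)))
      out$cohort <- unname(coh[out$individual_id])
    }
    out
  })
}

#' Simulate the reference panel
#'
#' Draws allele frequencies for every population and one reference sample
#' per population at the configured sizes.
#'
#' @param config A [sim_config()].
#' @return A list: `freqs` (from [sim_allele_freqs()]), `geno` (combined
#'   genotype table, one sample per population), `pools` (a [build_pools()]
#'   object), `config`.
#' @export
sim_reference_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  freqs <- sim_allele_freqs(config)
  geno <- lapply(config$pop_names, function(q) {
    sim_genotypes(freqs[freqs$pop == q, ], n = config$sample_sizes[q],
                  missing_rate = config$missing_rate,
                  seed = derive_seed(config$seed, paste0("ref-", q)), label = q)
  })
  geno <- dplyr::bind_rows(geno)
  geno <- as_geno_tbl(geno, loci = locus_names(config$n_loci), samples = config$pop_names)
  list(freqs = freqs, geno = geno, pools = build_pools(geno), config = config)
}

# region of a pool name / destination region of a pool
pool_region <- function(pool) ifelse(pool == "Kattegat", "Kattegat", "NorthSea")

# Daily longitude track: linear drift to the destination (directional) or
# stationary (nonmigratory), Gaussian noise, isolated single-day outliers.
sim_track_lons <- function(n_days, release_lon, dest_lon, noise_sd, outlier_rate) {
  if (n_days <= 0) return(numeric(0))
  base <- if (is.na(dest_lon)) {
    rep(release_lon, n_days)
  } else {
    arrive <- max(1, floor(0.7 * n_days))
    c(seq(release_lon, dest_lon, length.out = arrive),
      rep(dest_lon, n_days - arrive))
  }
  lon <- base + rnorm(n_days, 0, noise_sd)
  out_day <- runif(n_days) < outlier_rate
  if (any(out_day)) {
    # forbid consecutive outliers so no spurious run can ever be committed
    for (i in which(out_day)) if (i > 1 && out_day[i - 1]) out_day[i] <- FALSE
    jumps <- sample(c(-1, 1), sum(out_day), replace = TRUE) * runif(sum(out_day), 1.5, 3)
    lon[out_day] <- lon[out_day] + jumps
  }
  lon
}

#' Simulate a tagged cohort with known truth
#'
#' Generates the tagged fish: an origin pool, a genotype drawn from that
#' pool's frequencies, a release region, a behaviour (directional with
#' probability `p_migratory`, heading toward the origin region with
#' probability `philopatry_prob`, else the other region; nonmigratory fish
#' stay in the release region), and a daily-longitude track realising that
#' behaviour. When `behaviour_counts` is set in the config the five group
#' sizes are fixed and the origin is drawn conditionally (destination pool
#' with probability `philopatry_prob` for migrants; release-region pool for
#' residents). A Kattegat-released fish whose destination is its own region
#' is generated as nonmigratory.
#'
#' @param config A [sim_config()].
#' @param freqs Population frequency tibble from [sim_allele_freqs()].
#' @param seed Optional seed override.
#' @return A list: `fish` (tibble shaped like [read_track_table()] output
#'   plus nothing else), `geno` (genotype table, sample `tagged`), `truth`
#'   (tibble `fish_id`, `origin`, `behaviour`, `release_region`).
#' @export
sim_tagged_cohort <- function(config, freqs, seed = NULL) {
  stopifnot(inherits(config, "sim_config"))
  seed <- seed %||% config$seed
  n <- config$n_tagged
  ids <- sprintf("fish_%03d", seq_len(n))
  phi <- config$philopatry_prob
  pools <- config$pop_names
  other_pool <- function(q) pools[pools != q][1]

  truth <- with_seed(derive_seed(seed, "cohort-design"), {
    if (!is.null(config$behaviour_counts)) {
      bc <- config$behaviour_counts
      behaviour <- sample(rep(names(bc), bc))
      release <- ifelse(behaviour %in% c("SkagerrakToNorthSea", "SkagerrakToKattegat",
                                         "NonmigratorySkagerrak"),
                        "ESkagerrak", "Kattegat")
      home_pool <- dplyr::case_when(
        behaviour %in% c("SkagerrakToNorthSea", "KattegatToNorthSea") ~ "NorthSea_WSkagerrak",
        behaviour == "SkagerrakToKattegat" ~ "Kattegat",
        behaviour == "NonmigratorySkagerrak" ~ "NorthSea_WSkagerrak",
        behaviour == "NonmigratoryKattegat" ~ "Kattegat"
      )
      philo <- runif(n) < phi
      origin <- ifelse(philo, home_pool, vapply(home_pool, other_pool, character(1)))
    } else {
      origin <- sample(pools, n, replace = TRUE, prob = config$origin_mix)
      release <- sample(names(config$release_mix), n, replace = TRUE,
                        prob = config$release_mix)
      migratory <- runif(n) < config$p_migratory
      dest_region <- ifelse(runif(n) < phi, pool_region(origin),
                            ifelse(pool_region(origin) == "Kattegat", "NorthSea", "Kattegat"))
      behaviour <- dplyr::case_when(
        !migratory & release == "ESkagerrak" ~ "NonmigratorySkagerrak",
        !migratory & release == "Kattegat" ~ "NonmigratoryKattegat",
        dest_region == "NorthSea" & release == "ESkagerrak" ~ "SkagerrakToNorthSea",
        dest_region == "NorthSea" & release == "Kattegat" ~ "KattegatToNorthSea",
        dest_region == "Kattegat" & release == "ESkagerrak" ~ "SkagerrakToKattegat",
        TRUE ~ "NonmigratoryKattegat"  # Kattegat-released, Kattegat-bound: stays
      )
    }
    tibble(fish_id = ids, origin = origin, behaviour = behaviour,
           release_region = release)
  })

  geno <- dplyr::bind_rows(lapply(pools, function(q) {
    ids_q <- truth$fish_id[truth$origin == q]
    if (length(ids_q) == 0) return(NULL)
    g <- sim_genotypes(freqs[freqs$pop == q, ], n = length(ids_q),
                       missing_rate = config$missing_rate,
                       seed = derive_seed(seed, paste0("tagged-", q)), label = "tagged")
    g$individual_id <- rep(ids_q, times = nrow(g) / length(ids_q))
    g
  }))
  geno <- as_geno_tbl(geno, loci = locus_names(config$n_loci), samples = "tagged")

  fish <- with_seed(derive_seed(seed, "cohort-tracks"), {
    rows <- lapply(seq_len(n), function(i) {
      b <- truth$behaviour[i]
      release_region <- truth$release_region[i]
      if (release_region == "ESkagerrak") {
        r_lat <- 58.2 + rnorm(1, 0, 0.15)
        r_lon <- 11.2 + rnorm(1, 0, 0.15)
      } else {
        r_lat <- 56.8 + rnorm(1, 0, 0.2)
        r_lon <- 11.9 + rnorm(1, 0, 0.15)
      }
      dal <- sample(45:250, 1)
      release_date <- as.Date("2003-10-01") + sample(-15:45, 1)
      recapture_date <- release_date + dal
      dest <- switch(b,
        SkagerrakToNorthSea = ,
        KattegatToNorthSea = c(lat = 57.3, lon = 7.5),
        SkagerrakToKattegat = c(lat = 56.6, lon = 11.5),
        c(lat = r_lat, lon = r_lon))
      directional <- b %in% c("SkagerrakToNorthSea", "KattegatToNorthSea",
                              "SkagerrakToKattegat")
      lons <- sim_track_lons(dal, r_lon, if (directional) dest[["lon"]] else NA,
                             config$track_noise_sd, config$outlier_rate)
      tibble(
        fish_id = truth$fish_id[i],
        release_date = release_date, release_lat = r_lat, release_lon = r_lon,
        release_region = release_region,
        recapture_date = recapture_date,
        recapture_lat = dest[["lat"]] + rnorm(1, 0, 0.05),
        recapture_lon = dest[["lon"]] + rnorm(1, 0, 0.05),
        track = list(tibble(date = release_date + seq_len(dal), longitude = lons))
      )
    })
    dplyr::bind_rows(rows)
  })
  list(fish = fish, geno = geno, truth = truth)
}

#' Simulate a complete study
#'
#' One call producing everything the pipeline consumes: reference panel,
#' pooled references, and the tagged cohort with truth labels.
#'
#' @param config A [sim_config()].
#' @return A list: `freqs`, `ref_geno`, `pools`, `fish`, `fish_geno`,
#'   `truth`, `config`.
#' @export
sim_study <- function(config) {
  ref <- sim_reference_panel(config)
  cohort <- sim_tagged_cohort(config, ref$freqs)
  list(freqs = ref$freqs, ref_geno = ref$geno, pools = ref$pools,
       fish = cohort$fish, fish_geno = cohort$geno, truth = cohort$truth,
       config = config)
}
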