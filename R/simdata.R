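#' Simulation configuration for admixture-with-sweep scenarios
#'
#' Defines the study conditions of the bundled simulator: four differentiated
#' founder pools (an autochthonous Maghrebi-like component plus European-,
#' West/East-African- and Middle-Eastern-like sources), a single admixture
#' pulse \code{g} generations ago with exponential ancestry tract lengths,
#' and an optional selective sweep placed before admixture (in one component)
#' or after it (acting on local ancestry at a locus).
#'
#' @param seed integer RNG seed; every simulator output is a pure function of
#'   (config, seed).
#' @param n_sites number of biallelic sites (>= 2).
#' @param chrom_length_bp chromosome length in bp.
#' @param recomb_rate uniform recombination rate in Morgans per bp; genetic
#'   distance is \code{recomb_rate * physical distance} throughout.
#' @param ancestries ancestry component labels; the first is the target's
#'   autochthonous component.
#' @param pool_sizes haplotypes per founder pool (even, >= 4).
#' @param admix_proportions named fractions summing to 1; the default
#'   European-like proportion is 0.153, the genome-wide average estimated in
#'   western North African cohorts.
#' @param generations_since_admixture pulse age g in generations.
#' @param cohort_size number of diploid target individuals sampled.
#' @param sweep optional list: component (ancestry label or
#'   \code{"target_post_admixture"}), locus_bp, s (>= 0), generations,
#'   p0 (initial favoured-allele frequency in (0,1)).
#' @param target_fst Balding-Nichols divergence parameter controlling the
#'   mean pairwise differentiation of the founder pools.
#' @param n_founders distinct founder haplotypes per pool; pool haplotypes
#'   are recombinant mosaics of these, so the pools carry linkage
#'   disequilibrium.
#' @param founder_scramble_gens effective generations of recombination used
#'   to build the founder mosaics (sets the background LD scale).
#' @param post_admixture_popsize haplotype count of the admixed population
#'   simulated during post-admixture selection; the cohort is sampled from it
#'   at the end, so small-sample drift does not contaminate the ancestry
#'   dosage field.
#' @param sweep_popsize haplotype count of the population simulated during a
#'   pre-admixture sweep (see \code{\link{apply_sweep}}).
#' @param chrom chromosome label.
#' @return list of class \code{sim_config}.
#' @export
sim_config <- function(seed = 1L,
                       n_sites = 2000L,
                       chrom_length_bp = 2.5e7,
                       recomb_rate = 3e-8,
                       ancestries = c("MAG", "EUR", "WEA", "MEA"),
                       pool_sizes = 300L,
                       admix_proportions = c(MAG = 0.55, EUR = 0.153,
                                             WEA = 0.20, MEA = 0.097),
                       generations_since_admixture = 10L,
                       cohort_size = 100L,
                       sweep = NULL,
                       target_fst = 0.10,
                       n_founders = 150L,
                       founder_scramble_gens = 100,
                       post_admixture_popsize = 5000L,
                       sweep_popsize = 2500L,
                       chrom = "1") {
  q <- admix_proportions
  if (is.null(names(q))) names(q) <- ancestries
  if (!setequal(names(q), ancestries))
    stop("admix_proportions must be named by the ancestry labels")
  q <- q[ancestries]
  if (abs(sum(q) - 1) > 1e-9) stop("admixture proportions must sum to 1")
  if (n_sites < 2L) stop("invalid config: n_sites < 2")
  if (pool_sizes < 4L) stop("invalid config: pool size < 4")
  if (pool_sizes %% 2L != 0L) stop("pool size must be even")
  if (!is.null(sweep)) {
    if (!is.null(sweep$s) && sweep$s < 0) stop("selection coefficient s must be >= 0")
    if (!is.null(sweep$p0) && (sweep$p0 <= 0 || sweep$p0 >= 1))
      stop("p0 must be in (0, 1)")
    if (!is.null(sweep$locus_bp) &&
        (sweep$locus_bp < 0 || sweep$locus_bp >= chrom_length_bp))
      stop("sweep locus outside the chromosome")
  }
  structure(list(seed = as.integer(seed), n_sites = as.integer(n_sites),
                 chrom_length_bp = as.numeric(chrom_length_bp),
                 recomb_rate = recomb_rate, ancestries = ancestries,
                 pool_sizes = as.integer(pool_sizes), admix_proportions = q,
                 generations_since_admixture = as.integer(generations_since_admixture),
                 cohort_size = as.integer(cohort_size), sweep = sweep,
                 target_fst = target_fst, n_founders = as.integer(n_founders),
                 founder_scramble_gens = founder_scramble_gens,
                 post_admixture_popsize = as.integer(post_admixture_popsize),
                 sweep_popsize = as.integer(sweep_popsize),
                 chrom = chrom),
            class = "sim_config")
}

# internal: one mosaic haplotype copied from rows of `src` with breakpoints
# drawn as a Poisson process of `rate_bp` per bp
mosaic_row <- function(src, positions, chrom_len, rate_bp, donors = NULL) {
  n_src <- nrow(src)
  k <- stats::rpois(1L, rate_bp * chrom_len)
  if (k == 0L) {
    d <- if (is.null(donors)) sample.int(n_src, 1L) else sample(donors, 1L)
    return(src[d, ])
  }
  cuts <- findInterval(sort(stats::runif(k) * chrom_len), positions)
  b <- unique(c(0L, cuts, length(positions)))
  out <- integer(length(positions))
  for (s in seq_len(length(b) - 1L)) {
    idx <- (b[s] + 1L):b[s + 1L]
    d <- if (is.null(donors)) sample.int(n_src, 1L) else sample(donors, 1L)
    out[idx] <- src[d, idx]
  }
  out
}

#' Build differentiated founder pools
#'
#' Per-site derived-allele frequencies for each pool are Balding-Nichols
#' draws around a shared ancestral frequency (uniform on 0.05-0.95) with
#' divergence parameter \code{target_fst}; each pool's haplotypes are
#' recombinant mosaics of \code{n_founders} Bernoulli founder haplotypes, so
#' the pools carry realistic within-pool linkage disequilibrium.
#'
#' @param cfg a \code{sim_config}.
#' @return named list of \code{hap_matrix} pools (one per ancestry) sharing
#'   one site map, with attributes \code{variants} (a \code{variant_table}
#'   whose REF is the ancestral allele) and \code{p_anc}.
#' @export
build_founder_pools <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  L <- cfg$n_sites
  positions <- sort(sample.int(cfg$chrom_length_bp - 1L, L))
  p_anc <- stats::runif(L, 0.05, 0.95)
  FF <- cfg$target_fst
  K <- cfg$n_founders
  rate_bp <- cfg$founder_scramble_gens * cfg$recomb_rate
  pools <- list()
  for (lab in cfg$ancestries) {
    pk <- stats::rbeta(L, p_anc * (1 - FF) / FF, (1 - p_anc) * (1 - FF) / FF)
    founders <- matrix(stats::rbinom(K * L, 1L, rep(pk, each = K)), nrow = K)
    a <- matrix(0L, cfg$pool_sizes, L)
    for (i in seq_len(cfg$pool_sizes))
      a[i, ] <- mosaic_row(founders, positions, cfg$chrom_length_bp, rate_bp)
    pools[[lab]] <- hap_matrix(a, positions, cfg$chrom,
                               sprintf("%s_S%03d", lab,
                                       seq_len(cfg$pool_sizes / 2L)))
  }
  vt <- variant_table(cfg$chrom, positions, sprintf("snp%05d", seq_len(L)),
                      ref = "A", alt = "G", aa = "A")
  attr(pools, "variants") <- vt
  attr(pools, "p_anc") <- p_anc
  pools
}

#' Deterministic haploid selection trajectory
#'
#' Iterates \eqn{p' = p(1+s) / (1+ps)} for the given number of generations.
#'
#' @param p0 initial favoured-allele frequency.
#' @param s selection coefficient (>= 0).
#' @param generations number of generations.
#' @return numeric vector of length \code{generations + 1} starting at p0.
#' @export
sweep_trajectory <- function(p0, s, generations) {
  p <- numeric(generations + 1L)
  p[1L] <- p0
  for (t in seq_len(generations))
    p[t + 1L] <- p[t] * (1 + s) / (1 + p[t] * s)
  p
}

# internal: sample k elements from an index vector (safe for length 1)
pick_from <- function(v, k) v[sample.int(length(v), k, replace = TRUE)]

#' Apply a selective sweep to a founder pool
#'
#' The favoured (derived) allele's frequency follows the deterministic
#' haploid-selection recursion \eqn{p' = p(1+s)/(1+ps)}: in each generation
#' the pool is resampled so that exactly \code{round(p_t n)} children carry
#' the favoured allele, the chromosome segment containing the locus being
#' copied from a carrier (resp. non-carrier) parent and the remaining
#' segments from random parents, with per-meiosis recombination at
#' \code{recomb_rate} per bp. This yields both the frequency shift and the
#' hitchhiking haplotype signature. The locus column is first reset so the
#' favoured allele starts at \code{round(p0 n)} copies (at least one).
#'
#' A sweep lasting hundreds of generations in a panel-sized population would
#' add coalescent drift that a realistically sized population would not
#' experience, so the selected phase is simulated with the standard
#' population-size rescaling: with \eqn{\lambda =} \code{round(popsize / n)},
#' the pool runs \code{generations /} \eqn{\lambda} steps at selection
#' \eqn{(1+s)^\lambda - 1} and recombination \eqn{\lambda r}. This leaves the
#' allele-frequency trajectory exact (the recursion is linear in logit space),
#' and preserves the drift ratio t/N, the carrier coalescence intensity and
#' the hitchhiking scale r t. Resampling stops early once the favoured allele
#' is fixed (the selected phase is then over).
#'
#' @param pool a \code{hap_matrix} founder pool.
#' @param locus site index of the selected SNP.
#' @param s selection coefficient (>= 0).
#' @param generations generations of selection.
#' @param p0 initial favoured-allele frequency (0 < p0 < 1).
#' @param seed RNG seed.
#' @param recomb_rate Morgans per bp.
#' @param chrom_length_bp chromosome length in bp.
#' @param popsize effective haplotype population size the sweep emulates
#'   (sets the rescaling factor; \code{popsize = } pool size disables
#'   rescaling).
#' @return the resampled \code{hap_matrix}.
#' @export
apply_sweep <- function(pool, locus, s, generations, p0, seed,
                        recomb_rate = 3e-8, chrom_length_bp = NULL,
                        popsize = 2500L) {
  set.seed(seed)
  if (s < 0) stop("s must be >= 0")
  if (p0 <= 0 || p0 >= 1) stop("p0 must be in (0, 1)")
  a <- pool$alleles
  n <- nrow(a)
  L <- ncol(a)
  if (locus < 1L || locus > L) stop("locus out of range")
  if (!any(a[, locus] == 1L, na.rm = TRUE)) stop("favoured allele absent at locus")
  if (is.null(chrom_length_bp)) chrom_length_bp <- max(pool$positions) + 1

  lambda <- max(1L, as.integer(round(popsize / n)))
  n_steps <- as.integer(ceiling(generations / lambda))
  s_eff <- (1 + s)^lambda - 1
  r_eff <- recomb_rate * lambda

  m0 <- max(1L, round(p0 * n))
  if (m0 >= n) stop("p0 incompatible with pool size")
  cur <- which(a[, locus] == 1L)
  if (length(cur) > m0)
    a[cur[sample.int(length(cur), length(cur) - m0)], locus] <- 0L
  if (length(cur) < m0) {
    non <- setdiff(seq_len(n), cur)
    a[non[sample.int(length(non), m0 - length(cur))], locus] <- 1L
  }
  traj <- sweep_trajectory(m0 / n, s_eff, n_steps)
  pos <- pool$positions
  rate <- r_eff * chrom_length_bp
  for (t in seq_len(n_steps)) {
    carriers <- which(a[, locus] == 1L)
    if (length(carriers) == n) break    # fixed: selection phase over
    m_t <- min(n, max(round(traj[t + 1L] * n), length(carriers)))
    noncar <- setdiff(seq_len(n), carriers)
    anew <- matrix(0L, n, L)
    is_car <- seq_len(n) <= m_t
    k <- stats::rpois(n, rate)
    plain <- which(k == 0L)
    if (length(plain)) {
      pc <- plain[is_car[plain]]
      pn <- plain[!is_car[plain]]
      if (length(pc))
        anew[pc, ] <- a[pick_from(carriers, length(pc)), , drop = FALSE]
      if (length(pn))
        anew[pn, ] <- a[pick_from(noncar, length(pn)), , drop = FALSE]
    }
    for (i in which(k > 0L)) {
      cuts <- findInterval(sort(stats::runif(k[i]) * chrom_length_bp), pos)
      b <- unique(c(0L, cuts, L))
      nseg <- length(b) - 1L
      par <- sample.int(n, nseg, replace = TRUE)
      segloc <- findInterval(locus - 1L, b)   # segment s covers sites b[s]+1 .. b[s+1]
      par[segloc] <- if (is_car[i]) pick_from(carriers, 1L) else pick_from(noncar, 1L)
      for (sgi in seq_len(nseg)) {
        idx <- (b[sgi] + 1L):b[sgi + 1L]
        anew[i, idx] <- a[par[sgi], idx]
      }
    }
    a <- anew
  }
  hap_matrix(a, pos, pool$chrom, pool$samples)
}

# internal: simulate n_hap admixed haplotypes from the pools under the pulse
# model; tracts are returned as per-haplotype end/label vectors
draw_admixed_haps <- function(pools, cfg, n_haps, hap_ids) {
  labs <- cfg$ancestries
  miss <- setdiff(labs, names(pools))
  if (length(miss)) stop("missing pool(s) for ancestry: ", paste(miss, collapse = ", "))
  q <- cfg$admix_proportions[labs]
  Lbp <- cfg$chrom_length_bp
  rate <- cfg$generations_since_admixture * cfg$recomb_rate * Lbp
  pos <- pools[[1L]]$positions
  L <- length(pos)
  a <- matrix(0L, n_haps, L)
  ends <- vector("list", n_haps)
  labels <- vector("list", n_haps)
  for (h in seq_len(n_haps)) {
    k <- stats::rpois(1L, rate)
    bp <- if (k > 0L) sort(stats::runif(k) * Lbp) else numeric()
    e <- c(bp, Lbp)
    lab <- sample(labs, length(e), replace = TRUE, prob = q)
    # collapse runs of equal labels
    keep <- c(lab[-1L] != lab[-length(lab)], TRUE)
    e <- e[keep]; lab <- lab[keep]
    b <- c(0, e)
    for (s in seq_along(e)) {
      idx0 <- findInterval(b[s], pos) + 1L   # first site at/after tract start
      idx1 <- findInterval(e[s] - 1e-9, pos) # last site before tract end
      if (idx0 > idx1) next
      donor <- sample.int(n_hap(pools[[lab[s]]]), 1L)
      a[h, idx0:idx1] <- pools[[lab[s]]]$alleles[donor, idx0:idx1]
    }
    ends[[h]] <- e
    labels[[h]] <- lab
  }
  list(alleles = a, ends = ends, labels = labels, positions = pos,
       hap_ids = hap_ids)
}

tracts_from_lists <- function(ends, labels, hap_ids, chrom, chrom_len, all_labels) {
  n <- vapply(ends, length, integer(1L))
  df <- data.frame(haplotype_id = rep(hap_ids, n), chrom = chrom,
                   start = unlist(lapply(ends, function(e) c(0, e[-length(e)]))),
                   end = unlist(ends),
                   ancestry = unlist(labels), stringsAsFactors = FALSE)
  tract_set(df, chrom_len, labels = all_labels)
}

#' Simulate an admixed cohort by pulse admixture
#'
#' Each haplotype draws ancestry breakpoints as a Poisson process of rate
#' \code{g * r} per bp (so tract lengths are exponential with mean
#' \code{1/(g r)}), labels each tract independently with the admixture
#' proportions, and copies alleles from a random haplotype of the labelled
#' pool. The returned tracts are the ground truth used by the LAD scan.
#'
#' @param pools named list of founder pools sharing one site map.
#' @param cfg a \code{sim_config}.
#' @param seed optional seed (defaults to continuing the current RNG stream).
#' @return list: \code{hap} (\code{hap_matrix} of 2 x cohort_size
#'   haplotypes), \code{tracts} (\code{tract_set}).
#' @export
simulate_admixed_cohort <- function(pools, cfg, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_haps <- 2L * cfg$cohort_size
  samples <- sprintf("T%04d", seq_len(cfg$cohort_size))
  hap_ids <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
  d <- draw_admixed_haps(pools, cfg, n_haps, hap_ids)
  hm <- hap_matrix(d$alleles, d$positions, cfg$chrom, samples)
  tr <- tracts_from_lists(d$ends, d$labels, hap_ids, cfg$chrom,
                          cfg$chrom_length_bp, cfg$ancestries)
  list(hap = hm, tracts = tr)
}

# internal: ancestry label at a bp position for end/label tract vectors
label_at <- function(ends, labels, x) labels[findInterval(x, c(0, ends))]

# internal: sub-tract extraction of [x0, x1) from (ends, labels)
splice_tracts <- function(ends, labels, x0, x1) {
  i0 <- which(ends > x0)[1L]   # tract covering x0
  i1 <- which(ends >= x1)[1L]  # tract covering the point just before x1
  if (i1 == i0) return(list(ends = x1, labels = labels[i0]))
  list(ends = c(ends[i0:(i1 - 1L)], x1), labels = labels[i0:i1])
}

# internal: post-admixture selection on local ancestry. Haplotypes whose
# ancestry at the locus equals `favored` have fitness 1 + s; each generation
# every child copies segments (Poisson recombination) from fitness-weighted
# parents, splicing both alleles and ancestry tracts.
resample_post_admixture <- function(d, cfg, favored, locus_bp, s, generations) {
  n <- nrow(d$alleles)
  Lbp <- cfg$chrom_length_bp
  pos <- d$positions
  L <- length(pos)
  rate <- cfg$recomb_rate * Lbp
  anc <- vapply(seq_len(n), function(h) label_at(d$ends[[h]], d$labels[[h]], locus_bp),
                character(1L))
  for (t in seq_len(generations)) {
    w <- ifelse(anc == favored, 1 + s, 1)
    anew <- matrix(0L, n, L)
    ends2 <- vector("list", n)
    labels2 <- vector("list", n)
    anc2 <- character(n)
    k <- stats::rpois(n, rate)
    plain <- which(k == 0L)
    if (length(plain)) {
      par <- sample.int(n, length(plain), replace = TRUE, prob = w)
      anew[plain, ] <- d$alleles[par, , drop = FALSE]
      ends2[plain] <- d$ends[par]
      labels2[plain] <- d$labels[par]
      anc2[plain] <- anc[par]
    }
    for (i in which(k > 0L)) {
      bp <- sort(stats::runif(k[i]) * Lbp)
      b <- c(0, bp, Lbp)
      nseg <- length(b) - 1L
      par <- sample.int(n, nseg, replace = TRUE, prob = w)
      ee <- numeric(0)
      ll <- character(0)
      for (sgi in seq_len(nseg)) {
        x0 <- b[sgi]; x1 <- b[sgi + 1L]
        idx0 <- findInterval(x0, pos) + 1L
        idx1 <- findInterval(x1 - 1e-9, pos)
        if (idx0 <= idx1)
          anew[i, idx0:idx1] <- d$alleles[par[sgi], idx0:idx1]
        sp <- splice_tracts(d$ends[[par[sgi]]], d$labels[[par[sgi]]], x0, x1)
        ee <- c(ee, sp$ends)
        ll <- c(ll, sp$labels)
      }
      keep <- c(ll[-1L] != ll[-length(ll)], TRUE)
      ends2[[i]] <- ee[keep]
      labels2[[i]] <- ll[keep]
      anc2[i] <- label_at(ends2[[i]], labels2[[i]], locus_bp)
    }
    d$alleles <- anew
    d$ends <- ends2
    d$labels <- labels2
    anc <- anc2
  }
  d
}

#' Simulate a named selection scenario with ground truth
#'
#' Scenarios: \code{neutral} (no sweep); \code{private_sweep} (sweep in the
#' autochthonous component before admixture); \code{shared_sweep} (sweep in a
#' named source component before admixture, the post-sweep source matrix is
#' returned); \code{post_admixture_sweep} (after the pulse, haplotypes whose
#' local ancestry at the locus matches the favoured component have fitness
#' 1 + s for the sweep generations; selection runs in an expanded admixed
#' population from which the cohort is sampled at the end). Pre-admixture
#' sweep loci are chosen as the site nearest the requested position whose
#' ancestral frequency is low (0.05-0.25), the standard hard-sweep setting.
#'
#' Scenario defaults when the config omits them: private/shared s = 0.05,
#' 400 generations, p0 = 0.002 (a hard sweep from a single founder copy);
#' post-admixture s = 0.1, 15 generations;
#' shared and post-admixture sweeps act on the second ancestry
#' (European-like) by default; locus at the chromosome midpoint.
#'
#' @param name one of \code{"neutral"}, \code{"private_sweep"},
#'   \code{"shared_sweep"}, \code{"post_admixture_sweep"}.
#' @param cfg a \code{sim_config}.
#' @return object of class \code{scenario_bundle}: target (hap + tracts),
#'   sources (post-sweep founder pools), variants, truth (scenario, locus,
#'   favoured component/allele, parameters, seed, config).
#' @export
simulate_scenario <- function(name = c("neutral", "private_sweep",
                                       "shared_sweep", "post_admixture_sweep"),
                              cfg = sim_config()) {
  name <- match.arg(name)
  base <- cfg$seed
  pools <- build_founder_pools(cfg)   # seeds the stream with cfg$seed
  vt <- attr(pools, "variants")
  p_anc <- attr(pools, "p_anc")
  sw <- cfg$sweep
  defaults <- switch(name,
    neutral = NULL,
    private_sweep = list(component = cfg$ancestries[1L], s = 0.05,
                         generations = 400L, p0 = 0.002),
    shared_sweep = list(component = cfg$ancestries[2L], s = 0.05,
                        generations = 400L, p0 = 0.002),
    post_admixture_sweep = list(component = cfg$ancestries[2L], s = 0.1,
                                generations = 15L))
  if (!is.null(defaults)) {
    sw <- utils::modifyList(defaults, if (is.null(sw)) list() else sw)
    if (is.null(sw$locus_bp)) sw$locus_bp <- cfg$chrom_length_bp / 2
  }
  pos <- pools[[1L]]$positions
  locus <- NA_integer_
  if (!is.null(sw)) {
    if (name == "post_admixture_sweep") {
      locus <- which.min(abs(pos - sw$locus_bp))
    } else {
      # a hard sweep on a young mutation: the favoured allele must segregate
      # in the swept component but be (nearly) absent from the other pools
      comp_freq <- hap_freq(pools[[sw$component]]$alleles)
      other <- setdiff(cfg$ancestries, sw$component)
      other_max <- do.call(pmax, lapply(pools[other],
                                        function(p) hap_freq(p$alleles)))
      elig <- integer(0)
      for (cap in c(0.02, 0.05, 0.10, 1)) {
        elig <- which(comp_freq > 0 & other_max <= cap)
        if (length(elig)) break
      }
      locus <- elig[which.min(abs(pos[elig] - sw$locus_bp))]
    }
  }
  truth <- list(scenario = name, seed = base,
                locus_bp = if (is.na(locus)) NULL else pos[locus],
                locus_index = if (is.na(locus)) NULL else locus,
                component = if (is.null(sw)) NULL else sw$component,
                favored_allele = if (is.null(sw)) NULL
                                 else if (name == "post_admixture_sweep")
                                   sw$component else "derived",
                s = if (is.null(sw)) NULL else sw$s,
                generations = if (is.null(sw)) NULL else sw$generations,
                p0 = if (is.null(sw) || name == "post_admixture_sweep") NULL
                     else sw$p0)

  if (name %in% c("private_sweep", "shared_sweep")) {
    comp <- sw$component
    if (!comp %in% names(pools)) stop("unknown sweep component: ", comp)
    pools[[comp]] <- apply_sweep(pools[[comp]], locus, sw$s, sw$generations,
                                 sw$p0, seed = base + 1L,
                                 recomb_rate = cfg$recomb_rate,
                                 chrom_length_bp = cfg$chrom_length_bp,
                                 popsize = cfg$sweep_popsize)
  }

  if (name == "post_admixture_sweep") {
    set.seed(base + 2L)
    npop <- cfg$post_admixture_popsize
    d <- draw_admixed_haps(pools, cfg, npop, sprintf("P%05d", seq_len(npop)))
    d <- resample_post_admixture(d, cfg, sw$component, pos[locus],
                                 sw$s, sw$generations)
    pick <- sample.int(npop, 2L * cfg$cohort_size)
    samples <- sprintf("T%04d", seq_len(cfg$cohort_size))
    hap_ids <- paste0(rep(samples, each = 2L), "_", c(1L, 2L))
    hm <- hap_matrix(d$alleles[pick, , drop = FALSE], pos, cfg$chrom, samples)
    tr <- tracts_from_lists(d$ends[pick], d$labels[pick], hap_ids, cfg$chrom,
                            cfg$chrom_length_bp, cfg$ancestries)
    target <- list(hap = hm, tracts = tr)
  } else {
    target <- simulate_admixed_cohort(pools, cfg, seed = base + 2L)
  }

  attr(pools, "variants") <- NULL
  attr(pools, "p_anc") <- NULL
  structure(list(target = target, sources = pools, variants = vt,
                 truth = truth, config = cfg),
            class = "scenario_bundle")
}

#' @export
print.scenario_bundle <- function(x, ...) {
  cat(sprintf("scenario_bundle '%s': target %d haplotypes x %d sites, %d source pools\n",
              x$truth$scenario, n_hap(x$target$hap), n_sites(x$target$hap),
              length(x$sources)))
  if (!is.null(x$truth$locus_bp))
    cat(sprintf("  sweep: component %s, locus %s bp, s = %g, %d generations\n",
                x$truth$component, format(x$truth$locus_bp, big.mark = ","),
                x$truth$s, x$truth$generations))
  invisible(x)
}

#' Write / read a scenario bundle as plain files
#'
#' Emits the target and each source pool as VCF (phased GT, ancestral allele
#' in INFO/AA), the ground-truth tracts as TSV, the sample-to-population
#' table, and the truth record (including seed and config) as JSON, so a run
#' can be reproduced or inspected with standard tools. \code{read_bundle}
#' round-trips the haplotype data losslessly.
#'
#' @param bundle a \code{scenario_bundle}.
#' @param dir output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(bundle$target$hap, bundle$variants, file.path(dir, "target.vcf"))
  for (lab in names(bundle$sources))
    write_vcf(bundle$sources[[lab]], bundle$variants,
              file.path(dir, paste0("source_", lab, ".vcf")))
  write_tracts(bundle$target$tracts, file.path(dir, "tracts.tsv"))
  asg <- c(stats::setNames(rep("target", length(bundle$target$hap$samples)),
                           bundle$target$hap$samples),
           unlist(lapply(names(bundle$sources), function(lab)
             stats::setNames(rep(lab, length(bundle$sources[[lab]]$samples)),
                             bundle$sources[[lab]]$samples))))
  write_pop_spec(pop_spec(asg), file.path(dir, "populations.tsv"))
  cfg <- bundle$config
  jsonlite::write_json(list(truth = bundle$truth,
                            config = unclass(cfg)),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "truth.json"), simplifyVector = TRUE)
  cfg <- meta$config
  target <- read_vcf(file.path(dir, "target.vcf"))
  tracts <- read_tracts(file.path(dir, "tracts.tsv"), cfg$chrom_length_bp,
                        labels = cfg$ancestries)
  sources <- list()
  for (lab in cfg$ancestries) {
    f <- file.path(dir, paste0("source_", lab, ".vcf"))
    if (file.exists(f)) sources[[lab]] <- read_vcf(f)$hap
  }
  structure(list(target = list(hap = target$hap, tracts = tracts),
                 sources = sources, variants = target$variants,
                 truth = meta$truth, config = cfg),
            class = "scenario_bundle")
}
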