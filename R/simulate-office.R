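# Synthetic office simulator: touch logs and pre/post surface microbiota
# tables with a planted invader, a planted co-occurring "saliva" genus group,
# and ASVs under neutral vs. selected source-sink regimes.

#' Configuration for the synthetic office simulator
#'
#' Defaults describe a one-day office study: participants work from 8 a.m.
#' to 9 p.m. (13 h), each owning a pooled-hands surface, a face, a phone and
#' six private inanimate surfaces, alongside shared public surfaces. One
#' participant (the root carrier) is re-inoculated with an invader on their
#' hands approximately every 30 min. Touches move a fixed fraction of each
#' side's community mass to the other side; handwashing multiplies hand mass
#' by a survival factor.
#'
#' @param n_participants number of participants (default 24).
#' @param n_public_surfaces number of shared public surfaces (default 6).
#' @param duration_s experiment length in seconds (default 46800 = 13 h).
#' @param carrier_id participant index acting as root carrier (default 1).
#' @param inoculation_interval_s seconds between invader inoculations of the
#'   carrier's hands (default 1800 = 30 min).
#' @param inoculation_load community-mass units of invader added per
#'   inoculation (initial surface communities have mass near 1).
#' @param transfer_fraction fraction of each side's mass exchanged per touch.
#' @param touch_rate_own,touch_rate_public,touch_rate_social per-participant
#'   Poisson rates (events/s) of touching own surfaces, public surfaces, and
#'   another participant's surfaces. Social touches go predominantly to one
#'   designated friend.
#' @param handwash_rate_per_h handwashing events per participant per hour
#'   (default 0.4, the observed order of magnitude in office studies).
#' @param wash_survival multiplicative hand-community survival per wash.
#' @param n_asvs number of native (non-invader) ASVs.
#' @param n_cooccur_group number of co-occurring saliva-associated genera
#'   (default 6), each represented by two ASVs.
#' @param cooccur_mass mean per-participant saliva deposit mass.
#' @param seq_depth multinomial sequencing depth per sample.
#' @param seq_overdispersion Dirichlet-multinomial overdispersion of the
#'   sequencing draw (smaller = noisier counts, more dropout of rare taxa);
#'   amplicon count data are substantially overdispersed relative to a pure
#'   multinomial.
#' @param dirichlet_concentration concentration of the Dirichlet draws around
#'   the skin/environment profiles (larger = less inter-surface variability).
#' @param frac_hand_selected,frac_surface_selected fractions of native ASVs
#'   under hand- and surface-selection; the rest are neutral.
#' @param selection_boost fold-enrichment of selected ASVs in their
#'   preferred habitat profile.
#' @param friend_prob probability a social touch targets the designated
#'   friend rather than a random other participant.
#' @param handshake_prob probability a social touch is hand-to-hand.
#' @return A list of class `office_config`.
#' @export
office_config <- function(n_participants = 24,
                          n_public_surfaces = 6,
                          duration_s = 46800L,
                          carrier_id = 1L,
                          inoculation_interval_s = 1800L,
                          inoculation_load = 20,
                          transfer_fraction = 0.4,
                          touch_rate_own = 0.010,
                          touch_rate_public = 0.0002,
                          touch_rate_social = 0.0005,
                          handwash_rate_per_h = 0.4,
                          wash_survival = 0.1,
                          n_asvs = 150L,
                          n_cooccur_group = 6L,
                          cooccur_mass = 1.2,
                          seq_depth = 30000L,
                          seq_overdispersion = 300,
                          dirichlet_concentration = 50,
                          frac_hand_selected = 0.2,
                          frac_surface_selected = 0.3,
                          selection_boost = 8,
                          friend_prob = 0.8,
                          handshake_prob = 0.2) {
  cfg <- as.list(environment())
  if (cfg$n_participants < 2) stop("need at least 2 participants")
  if (cfg$transfer_fraction < 0 || cfg$transfer_fraction >= 1)
    stop("transfer_fraction must lie in [0, 1)")
  if (cfg$carrier_id < 1 || cfg$carrier_id > cfg$n_participants)
    stop("invalid carrier_id")
  rates <- c(cfg$touch_rate_own, cfg$touch_rate_public, cfg$touch_rate_social,
             cfg$handwash_rate_per_h)
  if (any(rates < 0)) stop("rates must be non-negative")
  structure(cfg, class = "office_config")
}

OWN_SURFACE_TYPES <- c("face", "phone", "mouse", "keyboard", "cup", "desk",
                       "chair_arm", "chair_seatback")
# faces and phones are touched least; desks and input devices most
OWN_TOUCH_WEIGHTS <- c(face = 0.05, phone = 0.05, mouse = 0.20,
                       keyboard = 0.20, cup = 0.10, desk = 0.25,
                       chair_arm = 0.10, chair_seatback = 0.05)
SOCIAL_TOUCH_WEIGHTS <- c(desk = 0.40, chair_arm = 0.20,
                          chair_seatback = 0.15, cup = 0.10, mouse = 0.10,
                          keyboard = 0.05)
PUBLIC_TYPES_CYCLE <- c("door_handle", "door_button", "dispenser_button",
                        "printer_screen")
# swabbed area per surface type relative to a hand contact patch; a touch
# only engages one patch of a large surface, so exchange with it is slower
# and deposited mass is diluted into a larger resident community
SURFACE_AREA <- c(hand = 1, face = 2, phone = 2, mouse = 2, cup = 2,
                  keyboard = 6, chair_arm = 4, chair_seatback = 8, desk = 30,
                  door_handle = 1, door_button = 1, dispenser_button = 1,
                  printer_screen = 2)
SALIVA_GENERA <- c("Streptococcus", "Haemophilus", "Neisseria",
                   "Actinomyces", "Rothia", "Gemella")
INVADER_SPLIT <- c(0.4, 0.3, 0.2, 0.1)  # mixture of the 4 invader ASVs

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

#' Simulate an office fomite-transmission experiment
#'
#' Generates a full ground-truthed scenario: (1) per-surface initial
#' communities drawn from Dirichlet distributions around a skin profile
#' (hands, faces) or an environment profile (all other surfaces), with
#' hand-selected ASVs enriched in the skin profile, surface-selected ASVs in
#' the environment profile, and neutral ASVs at exactly equal expected mass
#' in both; (2) a joint "saliva" deposit of the co-occurring genus group on
#' each participant's phone, cup and desk, scaled by a shared per-participant
#' emission intensity so the group co-varies across surfaces; (3) touch
#' events as independent Poisson streams (own, public, social-to-friend)
#' over the day; (4) symmetric proportional mass exchange at each touch;
#' (5) periodic invader inoculation of the carrier's hands; (6) Poisson
#' handwashing; (7) multinomial sequencing counts at fixed depth. Pre-
#' experiment samples are drawn from the initial hand/face/phone communities
#' and contain no invader.
#'
#' @param cfg an [office_config()].
#' @param seed integer seed; the same cfg and seed give bit-identical output.
#' @return A list of class `office_sim` with elements `touch_log`
#'   (data.frame time_s, surface_u, surface_v), `counts_pre` and
#'   `counts_post` ([count_table()]s), `taxonomy` ([taxonomy_map()]), and
#'   `truth` (invader ASV ids, carrier id, friend map, co-occurring genera,
#'   per-ASV neutrality regime, expected skin/environment mass profiles).
#' @export
generate_office <- function(cfg = office_config(), seed = NULL) {
  stopifnot(inherits(cfg, "office_config"))
  if (!is.null(seed)) set.seed(seed)
  np <- cfg$n_participants
  pid <- sprintf("P%02d", seq_len(np))
  carrier <- pid[cfg$carrier_id]

  ## ---- taxa and profiles -------------------------------------------------
  n_bg <- cfg$n_asvs
  asv_ids <- sprintf("asv%04d", seq_len(n_bg))
  inv_ids <- sprintf("inv_asv%d", 1:4)
  taxa <- c(asv_ids, inv_ids)

  # genus assignment: the saliva group genera get 2 ASVs each, ~10% of the
  # rest stay unassigned, remaining ASVs map to synthetic genera (some shared)
  n_co <- cfg$n_cooccur_group
  co_genera <- SALIVA_GENERA[seq_len(min(n_co, length(SALIVA_GENERA)))]
  if (n_co > length(SALIVA_GENERA))
    co_genera <- c(co_genera,
                   sprintf("saliva_genus_%02d", seq_len(n_co - length(co_genera))))
  co_asv_idx <- seq_len(2 * n_co)             # first 2*n_co background ASVs
  genus <- character(n_bg)
  genus[co_asv_idx] <- rep(co_genera, each = 2)
  rest <- setdiff(seq_len(n_bg), co_asv_idx)
  n_un <- ceiling(0.1 * length(rest))
  unassigned_idx <- rest[seq_len(n_un)]
  genus[unassigned_idx] <- "unassigned"
  assigned <- setdiff(rest, unassigned_idx)
  n_gen <- max(1L, round(0.8 * length(assigned)))
  genus[assigned] <- sprintf("genus_%03d",
                             sort(sample.int(n_gen, length(assigned),
                                             replace = TRUE)))
  tax <- taxonomy_map(
    asv_id = taxa,
    genus = c(genus, rep("Lactobacillus", 4)),
    species = c(rep("unassigned", n_bg), rep("Lactobacillus_delbrueckii", 4)),
    invader = c(rep(FALSE, n_bg), rep(TRUE, 4)))

  # neutrality regimes partition the native ASVs; the co-occurrence group is
  # kept neutral so its planted signal is the saliva deposit, not selection
  regime <- rep("neutral", n_bg)
  names(regime) <- asv_ids
  eligible <- setdiff(seq_len(n_bg), co_asv_idx)
  n_hand <- round(cfg$frac_hand_selected * n_bg)
  n_surf <- round(cfg$frac_surface_selected * n_bg)
  sel <- sample(eligible, min(n_hand + n_surf, length(eligible)))
  regime[sel[seq_len(min(n_hand, length(sel)))]] <- "hand_selected"
  if (length(sel) > n_hand)
    regime[sel[(n_hand + 1):length(sel)]] <- "surface_selected"

  base <- exp(stats::rnorm(n_bg, 0, 1.2))
  # saliva-group taxa are rare on surfaces except through saliva deposits,
  # so their resident background mass is kept low
  base[co_asv_idx] <- base[co_asv_idx] * 0.1
  base <- base / sum(base)                     # mean community mass ~ 1
  skin_mass <- env_mass <- base
  skin_mass[regime == "hand_selected"] <-
    base[regime == "hand_selected"] * cfg$selection_boost
  env_mass[regime == "surface_selected"] <-
    base[regime == "surface_selected"] * cfg$selection_boost

  ## ---- surfaces ----------------------------------------------------------
  own_types <- c("hand", OWN_SURFACE_TYPES)
  surf_df <- data.frame(
    surface_id = c(as.vector(outer(pid, own_types, paste, sep = "_")),
                   sprintf("public_%s_%d",
                           PUBLIC_TYPES_CYCLE[(seq_len(cfg$n_public_surfaces) - 1) %%
                                                length(PUBLIC_TYPES_CYCLE) + 1],
                           seq_len(cfg$n_public_surfaces))),
    surface_type = c(rep(own_types, each = np),
                     PUBLIC_TYPES_CYCLE[(seq_len(cfg$n_public_surfaces) - 1) %%
                                          length(PUBLIC_TYPES_CYCLE) + 1]),
    owner = c(rep(pid, length(own_types)), rep("public", cfg$n_public_surfaces)),
    stringsAsFactors = FALSE)
  ns <- nrow(surf_df)
  sid <- surf_df$surface_id
  is_skin <- surf_df$surface_type %in% c("hand", "face")

  ## ---- initial communities ----------------------------------------------
  M0 <- matrix(0, ns, length(taxa), dimnames = list(sid, taxa))
  conc <- cfg$dirichlet_concentration
  area <- SURFACE_AREA[surf_df$surface_type]
  for (s in seq_len(ns)) {
    prof <- if (is_skin[s]) skin_mass else env_mass
    M0[s, seq_len(n_bg)] <-
      rdirichlet1(conc * prof / sum(prof)) * sum(prof) * area[s]
  }

  # joint saliva deposit on phone/cup/desk, shared intensity per participant
  saliva_int <- stats::rlnorm(np, meanlog = log(cfg$cooccur_mass), sdlog = 1.2)
  names(saliva_int) <- pid
  genus_w <- exp(-0.1 * (seq_len(n_co) - 1))  # mildly decreasing genus weights
  genus_w <- genus_w / sum(genus_w)
  asv_split <- c(0.6, 0.4)
  for (p in pid) {
    for (st in c("phone", "cup", "desk")) {
      s <- paste(p, st, sep = "_")
      dep <- saliva_int[p] * stats::rlnorm(1, 0, 0.3)
      add <- dep * rep(genus_w, each = 2) * rep(asv_split, n_co)
      M0[s, co_asv_idx] <- M0[s, co_asv_idx] + add
    }
  }
  M <- M0

  ## ---- event streams -----------------------------------------------------
  # friendships are mutual pairs (a random matching): interpersonal intimacy
  # is symmetric, so a one-directional designation would not be recoverable
  perm <- sample(pid)
  friend <- stats::setNames(character(np), pid)
  for (i in seq(1, np - 1, by = 2)) {
    friend[perm[i]] <- perm[i + 1]
    friend[perm[i + 1]] <- perm[i]
  }
  if (np %% 2 == 1) friend[perm[np]] <- perm[1]

  dur <- cfg$duration_s
  events <- list()
  # own-surface touches
  for (p in pid) {
    k <- stats::rpois(1, cfg$touch_rate_own * dur)
    if (k > 0) {
      tgt <- sample(names(OWN_TOUCH_WEIGHTS), k, replace = TRUE,
                    prob = OWN_TOUCH_WEIGHTS)
      events[[length(events) + 1]] <- data.frame(
        time = stats::runif(k, 0, dur), type = "touch",
        u = paste(p, "hand", sep = "_"), v = paste(p, tgt, sep = "_"),
        stringsAsFactors = FALSE)
    }
  }
  # public-surface touches
  pub_ids <- sid[surf_df$owner == "public"]
  for (p in pid) {
    k <- stats::rpois(1, cfg$touch_rate_public * dur)
    if (k > 0)
      events[[length(events) + 1]] <- data.frame(
        time = stats::runif(k, 0, dur), type = "touch",
        u = paste(p, "hand", sep = "_"),
        v = sample(pub_ids, k, replace = TRUE), stringsAsFactors = FALSE)
  }
  # social touches, predominantly toward the designated friend
  for (p in pid) {
    k <- stats::rpois(1, cfg$touch_rate_social * dur)
    if (k > 0) {
      partner <- ifelse(stats::runif(k) < cfg$friend_prob, friend[p],
                        sample(setdiff(pid, p), k, replace = TRUE))
      shake <- stats::runif(k) < cfg$handshake_prob
      tgt_type <- ifelse(shake, "hand",
                         sample(names(SOCIAL_TOUCH_WEIGHTS), k, replace = TRUE,
                                prob = SOCIAL_TOUCH_WEIGHTS))
      events[[length(events) + 1]] <- data.frame(
        time = stats::runif(k, 0, dur), type = "touch",
        u = paste(p, "hand", sep = "_"),
        v = paste(partner, tgt_type, sep = "_"), stringsAsFactors = FALSE)
    }
  }
  # handwashing
  for (p in pid) {
    k <- stats::rpois(1, cfg$handwash_rate_per_h / 3600 * dur)
    if (k > 0)
      events[[length(events) + 1]] <- data.frame(
        time = stats::runif(k, 0, dur), type = "wash",
        u = paste(p, "hand", sep = "_"), v = NA_character_,
        stringsAsFactors = FALSE)
  }
  # carrier inoculation
  ino_t <- if (cfg$inoculation_interval_s <= dur)
    seq(cfg$inoculation_interval_s, dur, by = cfg$inoculation_interval_s)
  else numeric(0)
  if (length(ino_t) > 0)
    events[[length(events) + 1]] <- data.frame(
      time = ino_t, type = "inoculate",
      u = paste(carrier, "hand", sep = "_"), v = NA_character_,
      stringsAsFactors = FALSE)

  ev <- if (length(events) > 0) do.call(rbind, events) else
    data.frame(time = numeric(), type = character(), u = character(),
               v = character(), stringsAsFactors = FALSE)
  ev <- ev[order(ev$time), , drop = FALSE]

  ## ---- dynamics ----------------------------------------------------------
  f <- cfg$transfer_fraction
  inv_cols <- match(inv_ids, taxa)
  iu <- match(ev$u, sid)
  iv <- match(ev$v, sid)
  for (e in seq_len(nrow(ev))) {
    if (ev$type[e] == "touch") {
      a <- iu[e]; b <- iv[e]
      if (a == b) next
      # symmetric patch exchange: each side contributes fraction f of the
      # community on one contact patch (1/area of the whole surface)
      da <- f / area[a] * M[a, ]; db <- f / area[b] * M[b, ]
      M[a, ] <- M[a, ] - da + db
      M[b, ] <- M[b, ] - db + da
    } else if (ev$type[e] == "wash") {
      M[iu[e], ] <- M[iu[e], ] * cfg$wash_survival
    } else {  # inoculate
      M[iu[e], inv_cols] <- M[iu[e], inv_cols] +
        cfg$inoculation_load * INVADER_SPLIT
    }
  }

  touch_log <- ev[ev$type == "touch", c("time", "u", "v")]
  names(touch_log) <- c("time_s", "surface_u", "surface_v")
  touch_log$time_s <- as.integer(floor(touch_log$time_s))
  rownames(touch_log) <- NULL

  ## ---- sequencing --------------------------------------------------------
  draw_counts <- function(mass_mat, suffix) {
    cm <- t(apply(mass_mat, 1, function(w) {
      if (sum(w) == 0) return(rep(0L, length(w)))
      # Dirichlet-multinomial: swabbing + amplification overdispersion
      p <- rdirichlet1(cfg$seq_overdispersion * w / sum(w))
      stats::rmultinom(1, cfg$seq_depth, p)[, 1]
    }))
    colnames(cm) <- taxa
    rownames(cm) <- paste(rownames(mass_mat), suffix, sep = "_")
    cm
  }
  pre_rows <- sid[surf_df$surface_type %in% c("hand", "face", "phone")]
  counts_pre_m <- draw_counts(M0[pre_rows, , drop = FALSE], "pre")
  counts_post_m <- draw_counts(M, "post")

  mk_meta <- function(rows, src, timepoint) {
    data.frame(sample_id = rows,
               experiment_id = "sim",
               surface_id = src$surface_id,
               surface_type = src$surface_type,
               owner = src$owner,
               timepoint = timepoint,
               is_carrier_owned = src$owner == carrier,
               stringsAsFactors = FALSE)
  }
  meta_pre <- mk_meta(rownames(counts_pre_m),
                      surf_df[match(pre_rows, sid), ], "pre")
  meta_post <- mk_meta(rownames(counts_post_m), surf_df, "post")

  truth <- list(
    invader_asv_ids = inv_ids,
    carrier_id = carrier,
    friend_map = as.list(friend),
    cooccur_genera = co_genera,
    neutrality_regime = as.list(regime),
    true_m = NA_real_,   # office dynamics are mechanistic, not Sloan-parametric
    skin_expected_mass = as.list(stats::setNames(skin_mass, asv_ids)),
    env_expected_mass = as.list(stats::setNames(env_mass, asv_ids)))

  structure(list(touch_log = touch_log,
                 counts_pre = count_table(counts_pre_m, meta_pre),
                 counts_post = count_table(counts_post_m, meta_post),
                 taxonomy = tax,
                 truth = truth,
                 config = cfg,
                 mass_initial = M0,   # diagnostic: pre-dynamics masses
                 mass_final = M),     # diagnostic: end-of-day masses
            class = "office_sim")
}

#' @export
print.office_sim <- function(x, ...) {
  cat("office_sim:", x$config$n_participants, "participants,",
      nrow(x$counts_post$counts), "post samples,",
      nrow(x$touch_log), "touch events\n")
  cat("  carrier:", x$truth$carrier_id, "| invader ASVs:",
      paste(x$truth$invader_asv_ids, collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated office scenario to plain-text files
#'
#' Writes `touch_log.csv`, `counts_pre.tsv`/`meta_pre.tsv`,
#' `counts_post.tsv`/`meta_post.tsv`, `taxonomy.tsv` and `truth.json` into
#' `out_dir`.
#'
#' @param sim an `office_sim` from [generate_office()].
#' @param out_dir output directory (created if missing).
#' @export
write_office <- function(sim, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(sim$touch_log, file.path(out_dir, "touch_log.csv"),
                   row.names = FALSE, quote = FALSE)
  write_count_table(sim$counts_pre, file.path(out_dir, "counts_pre.tsv"),
                    file.path(out_dir, "meta_pre.tsv"))
  write_count_table(sim$counts_post, file.path(out_dir, "counts_post.tsv"),
                    file.path(out_dir, "meta_post.tsv"))
  write_taxonomy(sim$taxonomy, file.path(out_dir, "taxonomy.tsv"))
  jsonlite::write_json(sim$truth, file.path(out_dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(sim)
}

#' Simulate sink communities under the Sloan neutral model
#'
#' Draws sink compositions from the stationary distribution of a
#' Hubbell-type birth-death process with migration from a fixed source: a
#' Dirichlet with concentration N*m and mean P, so each ASV's relative
#' abundance is marginally Beta(N*P_i*m, N*(1-P_i)*m). Counts represent the
#' finite community of N individuals: under the default `"community"` mode
#' the count of ASV i is floor(N * x_i), so an ASV is detected exactly when
#' its relative abundance exceeds the model's 1/N threshold; the
#' `"multinomial"` mode resamples N individuals multinomially, adding
#' sampling noise on top of the stationary composition.
#'
#' @param P source relative-abundance vector (sums to 1).
#' @param m migration parameter in (0, 1\].
#' @param N community size; >= 10.
#' @param n_samples number of sink samples to draw.
#' @param seed optional integer seed.
#' @param counts_mode `"community"` (default) or `"multinomial"`.
#' @return A [count_table()] of sink samples (surface_type "desk",
#'   timepoint "post").
#' @export
simulate_neutral_sink <- function(P, m, N, n_samples, seed = NULL,
                                  counts_mode = c("community", "multinomial")) {
  counts_mode <- match.arg(counts_mode)
  if (m <= 0 || m > 1) stop("m must lie in (0, 1]")
  if (N < 10) stop("N must be >= 10")
  if (abs(sum(P) - 1) > 1e-8) stop("P must sum to 1")
  if (!is.null(seed)) set.seed(seed)
  taxa <- names(P)
  if (is.null(taxa)) taxa <- sprintf("asv%04d", seq_along(P))
  cm <- matrix(0L, n_samples, length(P),
               dimnames = list(sprintf("sink%04d", seq_len(n_samples)), taxa))
  alpha <- N * m * P
  for (s in seq_len(n_samples)) {
    x <- rdirichlet1(alpha)
    cm[s, ] <- if (counts_mode == "community") as.integer(floor(N * x))
               else stats::rmultinom(1, N, x)[, 1]
  }
  meta <- data.frame(sample_id = rownames(cm), experiment_id = "neutral_sim",
                     surface_type = "desk", owner = "public",
                     timepoint = "post", stringsAsFactors = FALSE)
  count_table(cm, meta)
}
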