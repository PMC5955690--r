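# Experimental design of the cued go-nogo-change task and a generative
# behavioral model (reaction times + error types) standing in for
# participants.
#
# Cue conditions: EG (expecting go), EC (expecting change), EN (expecting
# nogo). Within EC/EN the rare target (change / nogo) occurs on a fixed
# fraction of trials; all other targets are the standard go triangle.
# Derived trial conditions: go, no-change, change, no-nogo, nogo.

CUE_CONDITIONS <- c("EG", "EC", "EN")

#' Specification of the cued go-nogo-change design
#'
#' Defaults reproduce the published task structure: 6 blocks of 160 trials
#' (960 trials), the three cue conditions equiprobable, rare targets on 25%
#' of EC/EN trials, a 100 ms cue followed after a 1 s inter-stimulus interval
#' by a 100 ms target, inter-trial intervals jittered between 1.3 and 1.6 s,
#' and the standard response hand switching after half the blocks.
#'
#' @param n_blocks number of blocks.
#' @param trials_per_block trials in each block.
#' @param p_condition named probabilities for cue conditions EG/EC/EN.
#' @param p_rare_target probability of the rare (change/nogo) target within
#'   EC and EN trials.
#' @param cue_duration_ms,isi_ms,target_duration_ms stimulus timing (ms).
#' @param iti_range_ms length-2 inter-trial interval range (ms), jittered
#'   uniformly.
#' @param hand_switch_block first block of the second half, at which the
#'   standard hand flips.
#' @param counterbalance_order `"RHB_first"` (right-hand blocks first) or
#'   `"LHB_first"`.
#' @param seed integer seed for trial-order randomization.
#' @return a `design_spec` object (validated list).
#' @export
design_spec <- function(n_blocks = 6L,
                        trials_per_block = 160L,
                        p_condition = c(EG = 1 / 3, EC = 1 / 3, EN = 1 / 3),
                        p_rare_target = 0.25,
                        cue_duration_ms = 100,
                        isi_ms = 1000,
                        target_duration_ms = 100,
                        iti_range_ms = c(1300, 1600),
                        hand_switch_block = n_blocks / 2 + 1,
                        counterbalance_order = c("RHB_first", "LHB_first"),
                        seed = 1L) {
  counterbalance_order <- match.arg(counterbalance_order)
  stopifnot(
    n_blocks >= 1, trials_per_block >= 1,
    all(p_condition >= 0), all(p_condition <= 1),
    abs(sum(p_condition) - 1) < 1e-9,
    p_rare_target >= 0, p_rare_target <= 1,
    length(iti_range_ms) == 2, iti_range_ms[1] <= iti_range_ms[2],
    setequal(names(p_condition), CUE_CONDITIONS)
  )
  structure(
    list(n_blocks = as.integer(n_blocks),
         trials_per_block = as.integer(trials_per_block),
         p_condition = p_condition[CUE_CONDITIONS],
         p_rare_target = p_rare_target,
         cue_duration_ms = cue_duration_ms, isi_ms = isi_ms,
         target_duration_ms = target_duration_ms,
         iti_range_ms = iti_range_ms,
         hand_switch_block = as.integer(hand_switch_block),
         counterbalance_order = counterbalance_order,
         seed = as.integer(seed)),
    class = "design_spec"
  )
}

#' Generate the trial table for one session
#'
#' Lays out cue/target identities and onsets for every trial. With
#' `exact_allocation = TRUE`, condition counts per block equal
#' `trials_per_block * p` rounded to integers (a non-integer split such as
#' 160/3 is resolved by rotating the remainder across blocks, so the session
#' total matches the probabilities exactly), and rare-target counts within
#' EC/EN match `p_rare_target` exactly; an allocation that cannot be realized
#' as integer counts raises an error naming the offending count.
#'
#' @param spec a [design_spec()].
#' @param exact_allocation logical; exact per-block counts (default) versus
#'   independent random draws per trial.
#' @return a `data.frame` (one row per trial): `trial`, `block`, `condition`
#'   (EG/EC/EN), `target_type` (standard/change/nogo), `cue_onset_s`,
#'   `target_onset_s`, `standard_hand` (left/right), plus empty response
#'   columns (`response`, `rt_ms`, `correct`) filled by [simulate_behavior()].
#' @export
generate_design <- function(spec, exact_allocation = TRUE) {
  stopifnot(inherits(spec, "design_spec"))
  rng <- local_rng(spec$seed)
  n_total <- spec$n_blocks * spec$trials_per_block

  cond_blocks <- vector("list", spec$n_blocks)
  if (exact_allocation) {
    # block x condition counts: floor allocation, remainder rotated across
    # blocks so session totals match the probabilities exactly
    base <- floor(spec$trials_per_block * spec$p_condition)
    rem_per_block <- spec$trials_per_block - sum(base)
    counts <- matrix(rep(base, each = spec$n_blocks), nrow = spec$n_blocks,
                     dimnames = list(NULL, CUE_CONDITIONS))
    if (rem_per_block > 0) {
      for (b in seq_len(spec$n_blocks)) {
        extra <- ((b - 1 + seq_len(rem_per_block) - 1) %% 3) + 1
        for (e in extra) counts[b, e] <- counts[b, e] + 1
      }
    }
    tot <- colSums(counts)
    if (any(abs(tot - n_total * spec$p_condition) > 1e-9)) {
      stop(sprintf("condition allocation not realizable: session counts %s vs target %s",
                   paste(tot, collapse = "/"),
                   paste(round(n_total * spec$p_condition, 2), collapse = "/")))
    }
    # rare targets: exact at session level within each of EC/EN, spread over
    # blocks by largest remainder
    rare_counts <- matrix(0L, spec$n_blocks, 3,
                          dimnames = list(NULL, CUE_CONDITIONS))
    for (cc in c("EC", "EN")) {
      n_rare_exact <- tot[cc] * spec$p_rare_target
      if (abs(n_rare_exact - round(n_rare_exact)) > 1e-9) {
        stop(sprintf("rare-target allocation not realizable: %.3f rare %s trials of %d",
                     n_rare_exact, cc, tot[cc]))
      }
      n_rare <- as.integer(round(n_rare_exact))
      per_block <- floor(counts[, cc] * spec$p_rare_target)
      left <- n_rare - sum(per_block)
      if (left > 0) {
        frac <- counts[, cc] * spec$p_rare_target - per_block
        add <- order(frac, decreasing = TRUE)[seq_len(left)]
        per_block[add] <- per_block[add] + 1L
      }
      rare_counts[, cc] <- per_block
    }
    for (b in seq_len(spec$n_blocks)) {
      conds <- rep(CUE_CONDITIONS, times = counts[b, ])
      tt <- rep("standard", length(conds))
      for (cc in c("EC", "EN")) {
        idx <- which(conds == cc)
        rare <- idx[sample.int(length(idx), rare_counts[b, cc])]
        tt[rare] <- if (cc == "EC") "change" else "nogo"
      }
      ord <- sample(length(conds))
      cond_blocks[[b]] <- data.frame(condition = conds[ord], target_type = tt[ord])
    }
  } else {
    for (b in seq_len(spec$n_blocks)) {
      conds <- sample(CUE_CONDITIONS, spec$trials_per_block, replace = TRUE,
                      prob = spec$p_condition)
      tt <- ifelse(conds == "EG", "standard",
             ifelse(stats::runif(length(conds)) < spec$p_rare_target,
                    ifelse(conds == "EC", "change", "nogo"), "standard"))
      cond_blocks[[b]] <- data.frame(condition = conds, target_type = tt)
    }
  }
  tab <- do.call(rbind, cond_blocks)
  tab$block <- rep(seq_len(spec$n_blocks), each = spec$trials_per_block)
  tab$trial <- seq_len(n_total)

  # onsets: 1 s lead-in, then cue + ISI + target + jittered ITI per trial
  iti <- stats::runif(n_total, spec$iti_range_ms[1], spec$iti_range_ms[2]) / 1000
  soa <- (spec$cue_duration_ms + spec$isi_ms) / 1000   # cue onset -> target onset
  trial_len <- soa + spec$target_duration_ms / 1000 + iti
  cue_onset <- 1 + cumsum(c(0, trial_len[-n_total]))
  tab$cue_onset_s <- cue_onset
  tab$target_onset_s <- cue_onset + soa

  first_hand <- if (spec$counterbalance_order == "RHB_first") "right" else "left"
  other_hand <- setdiff(c("left", "right"), first_hand)
  tab$standard_hand <- ifelse(tab$block < spec$hand_switch_block,
                              first_hand, other_hand)
  tab$response <- NA_character_
  tab$rt_ms <- NA_real_
  tab$correct <- NA
  rng()  # restore RNG state
  rownames(tab) <- NULL
  tab[, c("trial", "block", "condition", "target_type", "cue_onset_s",
          "target_onset_s", "standard_hand", "response", "rt_ms", "correct")]
}

#' Derived trial condition (go / no-change / change / no-nogo / nogo)
#' @param trials a trial table.
#' @return character vector.
#' @export
derived_condition <- function(trials) {
  ifelse(trials$condition == "EG", "go",
    ifelse(trials$condition == "EC",
           ifelse(trials$target_type == "change", "change", "no-change"),
           ifelse(trials$target_type == "nogo", "nogo", "no-nogo")))
}

#' Generative behavioral parameters
#'
#' Reaction times are drawn from a shifted log-normal distribution (right
#' skew typical of RT data), parameterized by the target mean and SD of each
#' derived condition plus a common shift. Default means/SDs follow the
#' published group pattern (go fastest, change slowest). Error types:
#' premature presses during the cue-target interval (rate per cue condition),
#' omissions and choice errors (per derived condition), and failed
#' inhibitions on nogo trials.
#'
#' @param rt_mean,rt_sd named numeric (go, `no-change`, `no-nogo`, change), ms.
#' @param rt_shift common log-normal shift (ms).
#' @param subject_sd between-subject SD of the RT location (ms).
#' @param premature named rates per cue condition (EG, EC, EN).
#' @param omission,choice_error named rates per responded derived condition.
#' @param failed_inhibition rate of presses on nogo trials.
#' @param seed integer.
#' @return a `behavior_params` object.
#' @export
behavior_params <- function(
    rt_mean = c(go = 250, `no-change` = 358, `no-nogo` = 354, change = 403),
    rt_sd = c(go = 100, `no-change` = 76, `no-nogo` = 84, change = 88),
    rt_shift = 100,
    subject_sd = 40,
    premature = c(EG = 0.098, EC = 0.0045, EN = 0.0034),
    omission = c(go = 0.002, `no-change` = 0.01, `no-nogo` = 0.005, change = 0.03),
    choice_error = c(go = 0.0, `no-change` = 0.01, `no-nogo` = 0.005, change = 0.06),
    failed_inhibition = 0.13,
    seed = 1L) {
  rates <- c(premature, omission, choice_error, failed_inhibition)
  stopifnot(all(rates >= 0), all(rates <= 1),
            all(rt_mean > rt_shift), all(rt_sd > 0))
  structure(
    list(rt_mean = rt_mean, rt_sd = rt_sd, rt_shift = rt_shift,
         subject_sd = subject_sd, premature = premature, omission = omission,
         choice_error = choice_error, failed_inhibition = failed_inhibition,
         seed = as.integer(seed)),
    class = "behavior_params"
  )
}

# log-normal (meanlog, sdlog) matching a target mean/sd after shift removal
#' @noRd
lnorm_from_moments <- function(m, s) {
  v <- log(1 + (s / m)^2)
  list(meanlog = log(m) - v / 2, sdlog = sqrt(v))
}

#' Simulate responses and reaction times for a trial table
#'
#' Fills the response columns of a generated trial table: premature presses
#' (uniform latency within the cue-target interval), omissions, choice
#' errors, failed inhibitions on nogo trials, and otherwise correct responses
#' with shifted log-normal RTs. Deterministic under `params$seed` (combined
#' with `subject` for cohort simulation).
#'
#' @param trials trial table from [generate_design()].
#' @param params a [behavior_params()].
#' @param subject integer subject index, offsets the RNG substream and the
#'   subject-level RT location.
#' @return the trial table with `response` (right/left/none/premature),
#'   `rt_ms` and `correct` filled.
#' @export
simulate_behavior <- function(trials, params, subject = 1L) {
  stopifnot(inherits(params, "behavior_params"))
  if (any(!is.na(trials$response)))
    stop("trial table already contains responses")
  rng <- local_rng(params$seed + 7919L * as.integer(subject))
  on.exit(rng())
  n <- nrow(trials)
  dcond <- derived_condition(trials)
  subj_shift <- stats::rnorm(1, 0, params$subject_sd)

  response <- rep("none", n)
  rt <- rep(NA_real_, n)

  prem <- stats::runif(n) < params$premature[trials$condition]
  response[prem] <- "premature"

  for (i in which(!prem)) {
    dc <- dcond[i]
    hand <- trials$standard_hand[i]
    alt_hand <- setdiff(c("left", "right"), hand)
    if (dc == "nogo") {
      if (stats::runif(1) < params$failed_inhibition) {
        response[i] <- hand
        rt[i] <- draw_rt(params, "no-nogo", subj_shift)
      }
      next
    }
    if (stats::runif(1) < params$omission[dc]) next
    correct_hand <- if (dc == "change") alt_hand else hand
    wrong <- stats::runif(1) < params$choice_error[dc]
    response[i] <- if (wrong) setdiff(c("left", "right"), correct_hand) else correct_hand
    rt[i] <- draw_rt(params, dc, subj_shift)
  }

  out <- trials
  out$response <- response
  out$rt_ms <- rt
  correct_hand <- ifelse(dcond == "change",
                         ifelse(trials$standard_hand == "right", "left", "right"),
                         trials$standard_hand)
  out$correct <- ifelse(dcond == "nogo", response == "none",
                        response == correct_hand)
  out
}

#' @noRd
draw_rt <- function(params, dcond, subj_shift) {
  p <- lnorm_from_moments(params$rt_mean[[dcond]] - params$rt_shift,
                          params$rt_sd[[dcond]])
  params$rt_shift + subj_shift + stats::rlnorm(1, p$meanlog, p$sdlog)
}

#' Behavioral summary per subject
#'
#' Mean RT per derived condition (correct, non-premature responded trials
#' only), accuracy per derived condition, premature rate per cue condition,
#' and failed-inhibition rate. Conditions with no valid RTs are reported as
#' `NA`, never zero.
#'
#' @param trials a responded trial table; needs a `subject` column when
#'   summarizing a cohort (added by the caller), otherwise a single subject
#'   is assumed.
#' @return a `data.frame`, one row per subject.
#' @export
behavioral_summary <- function(trials) {
  if (is.null(trials$subject)) trials$subject <- 1L
  dcond <- derived_condition(trials)
  rt_conds <- c("go", "no-change", "no-nogo", "change")
  out <- lapply(split(seq_len(nrow(trials)), trials$subject), function(idx) {
    tt <- trials[idx, ]
    dc <- dcond[idx]
    row <- list(subject = tt$subject[1])
    for (cc in rt_conds) {
      sel <- dc == cc & tt$correct & tt$response %in% c("left", "right")
      row[[paste0("rt_", cc)]] <- if (any(sel)) mean(tt$rt_ms[sel]) else NA_real_
    }
    for (cc in c(rt_conds, "nogo")) {
      sel <- dc == cc
      row[[paste0("acc_", cc)]] <- if (any(sel)) mean(tt$correct[sel]) else NA_real_
    }
    for (cu in CUE_CONDITIONS) {
      sel <- tt$condition == cu
      row[[paste0("premature_", cu)]] <-
        if (any(sel)) mean(tt$response[sel] == "premature") else NA_real_
    }
    sel <- dc == "nogo"
    row$failed_inhibition <-
      if (any(sel)) mean(tt$response[sel] %in% c("left", "right")) else NA_real_
    as.data.frame(row, check.names = FALSE)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Read/write trial tables as tab-separated text
#'
#' Times are seconds from recording start; a JSON sidecar (same path with
#' `.json` appended) stores the generating [design_spec()].
#' @param trials trial table; @param path file path; @param spec optional
#'   design spec to store in the sidecar.
#' @export
write_trial_table <- function(trials, path, spec = NULL) {
  utils::write.table(trials, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(spec)) {
    jsonlite::write_json(unclass(spec), paste0(path, ".json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Seed-scoped RNG: sets the seed, returns a restorer for the previous state.
#' @noRd
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}
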