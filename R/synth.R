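#' Modular source model for synthetic EEG
#'
#' Signal family for the synthetic cohorts: channels are grouped into
#' modules, each with one band-limited oscillatory source — a sinusoid with
#' a subject-level base phase, per-epoch phase jitter of half-width
#' `phase_lock` radians, and per-epoch frequency jitter inside its band.
#' Partial phase locking emulates task-evoked activity: it is what lets a
#' source survive epoch averaging, exactly as an event-related response
#' does, while the per-epoch jitter keeps epochs from being copies of one
#' another (`phase_lock = pi` makes phases fully random and the averaged
#' sources vanish into noise).
#'
#' Modules are coupled in partner pairs (1-2, 3-4, ...): a channel mixes
#' its own module's source with weight `within_weight`, its partner
#' module's source with a configurable between-module weight (the
#' group-contrast knob of [cohort_spec()]), and independent white noise.
#' Channel pairs sharing source variance come out of the coupling
#' estimator systematically higher, so module structure is recoverable
#' from the top-density edges: at zero between-module weight only
#' within-module pairs are coupled, while a large weight welds each
#' partner pair into one densely coupled block.
#'
#' @param channels number of channels (divisible by `n_modules`).
#' @param n_modules number of modules; even, so partner pairing is total.
#' @param freqs per-module source frequencies in Hz; defaults to an even
#'   spread inside the 9-34 Hz analysis band. Sources are separable only
#'   down to the spectral resolution of the analyzed window, so closely
#'   spaced frequencies leak into spurious coupling.
#' @param within_weight mixing weight of the channel's own module source.
#' @param noise_sd standard deviation of per-channel white noise.
#' @param freq_jitter half-width (Hz) of the per-epoch frequency jitter.
#' @param phase_lock half-width (radians) of the per-epoch phase jitter
#'   around the subject-level source phase.
#' @return a `source_model` list; `module` holds the channel assignment.
#' @export
source_model <- function(channels = 16L, n_modules = 8L, freqs = NULL,
                         within_weight = 1, noise_sd = 0.5,
                         freq_jitter = 0.5, phase_lock = 0.5) {
  if (channels %% n_modules != 0) {
    jdnet_stop("jdnet_bad_config", "channels (%d) must be divisible by n_modules (%d)",
               channels, n_modules)
  }
  if (n_modules %% 2 != 0) {
    jdnet_stop("jdnet_bad_config", "n_modules must be even (modules couple in partner pairs)")
  }
  if (is.null(freqs)) {
    freqs <- seq(12, 30, length.out = n_modules)
  }
  if (length(freqs) != n_modules) {
    jdnet_stop("jdnet_bad_config", "need one source frequency per module")
  }
  if (noise_sd < 0) jdnet_stop("jdnet_bad_config", "noise_sd must be >= 0")
  structure(list(channels = as.integer(channels),
                 n_modules = as.integer(n_modules),
                 module = rep(seq_len(n_modules), each = channels / n_modules),
                 freqs = freqs, within_weight = within_weight,
                 noise_sd = noise_sd, freq_jitter = freq_jitter,
                 phase_lock = phase_lock),
            class = "source_model")
}

#' Cohort specification for synthetic two-group studies
#'
#' Shapes and group contrast of a synthetic cohort mirroring the clinical
#' study design this pipeline targets: 13 subjects in group A vs 14 in
#' group B, 256 Hz epochs of 358 samples with 51 pre-stimulus samples
#' (1.40 s / 0.2 s at 256 Hz, rounded to the nearest sample), and a
#' per-subject epoch count drawn uniformly from 23-87. The group contrast
#' is carried by the between-module mixing weight: group A gets
#' `between_a`, group B `between_b`; equal weights make the groups
#' exchangeable (the null case). Channel count defaults to 16 so the full
#' pairwise coupling analysis stays fast; 128 matches the full montage.
#'
#' @param n_a,n_b group sizes (>= 3).
#' @param channels channels per subject.
#' @param fs sampling rate (Hz).
#' @param epoch_len samples per epoch.
#' @param prestim pre-stimulus samples per epoch.
#' @param epochs_range inclusive range the per-subject epoch count is drawn
#'   from.
#' @param between_a,between_b between-module mixing weight per group, in
#'   [0, 1].
#' @param model a [source_model()]; its `channels` must match.
#' @param seed master seed; every subject derives a private substream.
#' @return a `cohort_spec` list.
#' @export
cohort_spec <- function(n_a = 13L, n_b = 14L, channels = 16L, fs = 256,
                        epoch_len = 358L, prestim = 51L,
                        epochs_range = c(23L, 87L),
                        between_a = 0.0, between_b = 0.6,
                        model = source_model(channels), seed = 1L) {
  if (n_a < 3 || n_b < 3) jdnet_stop("jdnet_bad_config", "group sizes must be >= 3")
  if (between_a < 0 || between_a > 1 || between_b < 0 || between_b > 1) {
    jdnet_stop("jdnet_bad_config", "between-module weights must lie in [0, 1]")
  }
  if (model$channels != channels) {
    jdnet_stop("jdnet_bad_config", "source model has %d channels, spec asks %d",
               model$channels, channels)
  }
  if (prestim >= epoch_len) jdnet_stop("jdnet_bad_config", "prestim must be < epoch_len")
  structure(list(n_a = as.integer(n_a), n_b = as.integer(n_b),
                 channels = as.integer(channels), fs = fs,
                 epoch_len = as.integer(epoch_len),
                 prestim = as.integer(prestim),
                 epochs_range = as.integer(epochs_range),
                 between_a = between_a, between_b = between_b,
                 model = model, seed = as.integer(seed)),
            class = "cohort_spec")
}

#' Generate one synthetic subject
#'
#' Draws one epoched recording from the [source_model()]: module sources
#' get a subject-level uniform base phase; per epoch, each source is a
#' sinusoid at its jittered frequency (the band must lie inside
#' (0, fs/2)) with the base phase plus per-epoch phase jitter; a channel
#' is `within_weight * own source + between_weight * partner module's
#' source + white noise`. Bit-identical output for identical seeds.
#'
#' @param model a [source_model()].
#' @param spec a [cohort_spec()] providing fs, epoch geometry.
#' @param between_weight between-module mixing weight for this subject.
#' @param n_epochs number of epochs to draw.
#' @param seed integer seed for this subject's private stream.
#' @return an [epoched_recording()].
#' @export
generate_subject <- function(model, spec, between_weight, n_epochs, seed) {
  if (any(model$freqs + model$freq_jitter >= spec$fs / 2) || any(model$freqs - model$freq_jitter <= 0)) {
    jdnet_stop("jdnet_bad_config", "source band must lie inside (0, fs/2)")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  nc <- model$channels
  nm <- model$n_modules
  tt <- (seq_len(spec$epoch_len) - 1) / spec$fs
  k <- seq_len(nm)
  partner <- ifelse(k %% 2 == 1, k + 1L, k - 1L)
  base_phase <- stats::runif(nm, 0, 2 * pi)
  arr <- array(0, c(nc, spec$epoch_len, n_epochs))
  for (e in seq_len(n_epochs)) {
    f <- model$freqs + stats::runif(nm, -model$freq_jitter, model$freq_jitter)
    phase <- base_phase + stats::runif(nm, -model$phase_lock, model$phase_lock)
    src <- sapply(k, function(j) sin(2 * pi * f[j] * tt + phase[j]))
    mix <- model$within_weight * t(src[, model$module]) +
      between_weight * t(src[, partner[model$module]])
    arr[, , e] <- mix + matrix(stats::rnorm(nc * spec$epoch_len, 0, model$noise_sd),
                               nc, spec$epoch_len)
  }
  epoched_recording(arr, spec$fs, spec$prestim)
}

#' Generate a synthetic two-group cohort
#'
#' Emits `n_a + n_b` subjects with group labels; group A subjects mix
#' between-module sources with `between_a`, group B with `between_b`.
#' Per-subject epoch counts are drawn uniformly from `epochs_range`, and
#' each subject gets a private seed derived from the master seed, so the
#' whole cohort is reproducible end to end.
#'
#' @param spec a [cohort_spec()].
#' @return list of subjects, each a list with `rec`
#'   ([epoched_recording()]), `group` (`"A"`/`"B"`), `id`, `n_epochs`,
#'   `seed`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(spec$seed)
  n <- spec$n_a + spec$n_b
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n)
  n_epochs <- sample(seq(spec$epochs_range[1], spec$epochs_range[2]), n, replace = TRUE)
  groups <- rep(c("A", "B"), c(spec$n_a, spec$n_b))
  lapply(seq_len(n), function(i) {
    bw <- if (groups[i] == "A") spec$between_a else spec$between_b
    list(rec = generate_subject(spec$model, spec, bw, n_epochs[i], subj_seeds[i]),
         group = groups[i],
         id = sprintf("S%02d", i),
         n_epochs = n_epochs[i],
         seed = subj_seeds[i])
  })
}
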