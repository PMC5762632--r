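#' Canonical feature registry
#'
#' The classifier operates on a fixed, ordered set of 411 named scalar
#' features per recording, grouped into five blocks:
#'
#' * `time` (24): peak kinematics and impulse durations.
#' * `psd` (152): one-sided periodogram power of linear acceleration
#'   (10--200 Hz) and angular acceleration (10--180 Hz) in 10 Hz bins,
#'   per anatomical component and vector magnitude.
#' * `wt` (152): per-frequency maxima over time of the Morlet wavelet
#'   amplitude on the same channel/frequency grid.
#' * `wtdesc` (32): per-channel wavelet descriptors (peak amplitude, peak
#'   frequency, peak-time offset from the time-domain peak, 10% bandwidth).
#' * `model` (51): head-neck linkage-model features and angular/linear
#'   acceleration coupling-ratio statistics.
#'
#' The ordering is part of the method: sequential forward selection breaks
#' cost ties by lowest registry index, and serialized feature tables carry a
#' registry version header so that stored tables cannot silently drift.
#'
#' @return Character vector of 411 feature names, with attributes `blocks`
#'   (named integer vector of block sizes) and `version` (registry version
#'   string).
#' @examples
#' reg <- feature_registry()
#' length(reg)            # 411
#' attr(reg, "blocks")
#' @export
feature_registry <- function() {
  lin_ch <- c("ap", "lr", "is", "mag")
  ang_ch <- c("cor", "sag", "hor", "mag")
  lin_f <- seq(10L, 200L, by = 10L)
  ang_f <- seq(10L, 180L, by = 10L)

  time24 <- c(
    paste0("la_peak_", lin_ch),
    paste0("dv_peak_", lin_ch),
    paste0("aa_peak_", ang_ch),
    paste0("dw_peak_", ang_ch),
    paste0("la_fwhm_", lin_ch),
    paste0("aa_fwhm_", ang_ch)
  )

  psd152 <- c(
    unlist(lapply(lin_ch, function(ch) sprintf("la_psd_%s_%dhz", ch, lin_f))),
    unlist(lapply(ang_ch, function(ch) sprintf("aa_psd_%s_%dhz", ch, ang_f)))
  )

  wt152 <- c(
    unlist(lapply(lin_ch, function(ch) sprintf("la_wt_%s_%dhz", ch, lin_f))),
    unlist(lapply(ang_ch, function(ch) sprintf("aa_wt_%s_%dhz", ch, ang_f)))
  )

  desc <- c("peak_amp", "peak_freq", "peak_dt", "bw10")
  wtdesc32 <- c(
    unlist(lapply(lin_ch, function(ch) sprintf("la_wtdesc_%s_%s", ch, desc))),
    unlist(lapply(ang_ch, function(ch) sprintf("aa_wtdesc_%s_%s", ch, desc)))
  )

  joint <- c("hn_lr", "hn_is", "neck_ap", "neck_lr", "neck_is")
  points <- c("torso_base", "head_base", "head_cog")
  pairs <- c("cor_lr", "cor_is", "sag_ap", "sag_is", "hor_ap", "hor_lr")
  model51 <- c(
    "nm_signmatch_lr", "nm_signmatch_is",
    paste0("nm_angle_", joint),
    paste0("nm_angvel_", joint),
    paste0("nm_angacc_", joint),
    unlist(lapply(points, function(p) sprintf("nm_%s_%s", p, c("disp", "vel", "acc")))),
    paste0("nm_cog_disp_", c("ap", "lr", "is")),
    paste0("nm_cog_vel_", c("ap", "lr", "is")),
    "nm_base_offset",
    unlist(lapply(pairs, function(p) sprintf("cr_%s_%s", p, c("mean", "sd", "peak"))))
  )

  reg <- c(time24, psd152, wt152, wtdesc32, model51)
  stopifnot(length(reg) == 411L, !anyDuplicated(reg))
  attr(reg, "blocks") <- c(time = length(time24), psd = length(psd152),
                           wt = length(wt152), wtdesc = length(wtdesc32),
                           model = length(model51))
  attr(reg, "version") <- REGISTRY_VERSION
  reg
}

REGISTRY_VERSION <- "1"

#' Stable checksum of the registry name list
#'
#' Platform-independent hash of the canonical ordered feature names, used to
#' assert that two runs (or a stored feature table and the installed package)
#' agree on the registry. A simple polynomial rolling hash over the UTF-8
#' bytes of the collapsed name list; stability across platforms matters more
#' than cryptographic strength.
#'
#' @param registry Character vector of feature names; defaults to
#'   [feature_registry()].
#' @return A character scalar (hexadecimal digest).
#' @export
registry_hash <- function(registry = feature_registry()) {
  bytes <- utf8ToInt(paste(registry, collapse = "|"))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

#' Block membership of registry features
#'
#' @param registry Registry name vector from [feature_registry()].
#' @return Factor of length 411 giving the block of each feature, levels
#'   `time`, `psd`, `wt`, `wtdesc`, `model`.
#' @export
registry_blocks <- function(registry = feature_registry()) {
  blocks <- attr(registry, "blocks")
  factor(rep(names(blocks), blocks), levels = names(blocks))
}

#' Identify low-frequency spectral features
#'
#' Convenience predicate for the 10--30 Hz power-spectral-density and
#' per-frequency wavelet features, the group the screening statistics and
#' forward selection single out on impact cohorts.
#'
#' @param names Character vector of registry feature names.
#' @return Logical vector: `TRUE` for PSD/WT per-frequency features at
#'   10, 20 or 30 Hz.
#' @export
is_low_freq_feature <- function(names) {
  grepl("^(la|aa)_(psd|wt)_(ap|lr|is|cor|sag|hor|mag)_(10|20|30)hz$", names)
}
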