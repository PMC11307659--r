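# Per-image quality statistics and outlier flagging with site-level discard.

#' Compute quality-control statistics for one image
#'
#' Reports the focus score, intensity sum, median, standard deviation and
#' the 0.01/0.25/0.75/0.99 intensity quantiles (linear interpolation
#' between order statistics, R's type-7 definition). The focus score is the
#' slope of the image's radially averaged log power spectrum against log
#' spatial frequency: blurring suppresses high frequencies and steepens the
#' decay, so higher (less negative) values mean sharper images. It is NA
#' for constant images.
#'
#' @param image 2-D nonnegative numeric matrix.
#' @param plate,well,site,channel identity copied into the record.
#' @return a one-row data frame (a QC record).
#' @export
compute_qc <- function(image, plate = NA_character_, well = NA_character_,
                       site = NA_integer_, channel = NA_character_) {
  if (!is.matrix(image) || length(image) == 0) {
    stop("`image` must be a non-empty 2-D matrix")
  }
  if (any(image < 0, na.rm = TRUE)) stop("`image` must be nonnegative")
  q <- stats::quantile(image, c(0.01, 0.25, 0.75, 0.99), names = FALSE,
                       type = 7)
  data.frame(plate = plate, well = well, site = site, channel = channel,
             focus_score = focus_score(image),
             intensity_sum = sum(image),
             intensity_median = stats::median(image),
             intensity_sd = stats::sd(image),
             q01 = q[1], q25 = q[2], q75 = q[3], q99 = q[4],
             saturated_fraction = mean(image >= 1 - 1e-6),
             pass = NA, fail_reason = "",
             stringsAsFactors = FALSE)
}

#' Power-spectrum focus score
#'
#' @param image numeric matrix.
#' @param fmin,fmax frequency band (cycles/pixel) over which the log-log
#'   slope is fitted.
#' @return the slope (higher = sharper); NA for constant images.
#' @export
focus_score <- function(image, fmin = 0.05, fmax = 0.45) {
  v <- image - mean(image)
  if (sum(abs(v)) == 0) return(NA_real_)
  P <- Mod(stats::fft(v))^2
  nr <- nrow(image); nc <- ncol(image)
  fy <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1)) / nr
  fx <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1)) / nc
  fr <- sqrt(outer(fy^2, fx^2, "+"))
  sel <- fr >= fmin & fr <= fmax & P > 0
  if (sum(sel) < 10) return(NA_real_)
  stats::coef(stats::lm(log(P[sel]) ~ log(fr[sel])))[[2]]
}

#' Outlier-flagging policy for QC records
#'
#' Automatic surrogate for histogram inspection: per plate and channel,
#' images fail when their focus score drops more than `k_mad` robust
#' deviations (MAD, with an IQR fallback when the MAD degenerates) below
#' the median, when their intensity sum leaves the median +/- `k_mad` MAD
#' band, when more than `max_saturated_fraction` of pixels sit at the top
#' of the dynamic range, or when they are entirely blank (sd = 0).
#'
#' @param k_mad robust threshold multiplier (default 5).
#' @param max_saturated_fraction tolerated fraction of saturated pixels.
#' @return a `qc_policy`.
#' @export
qc_policy <- function(k_mad = 5, max_saturated_fraction = 0.05) {
  structure(list(k_mad = k_mad,
                 max_saturated_fraction = max_saturated_fraction),
            class = "qc_policy")
}

#' Flag outlier images and discard whole sites
#'
#' Applies the policy per (plate, channel) group, then enforces the
#' site-level rule: if any channel of a site fails, every image of that
#' site fails, the siblings with reason `"sibling_channel_failed"`. The
#' number of passing images per site is therefore always 0 or the full
#' channel count.
#'
#' @param records data frame of QC records from [compute_qc()].
#' @param policy a [qc_policy()].
#' @return the records with `pass` and `fail_reason` filled in.
#' @export
flag_outliers <- function(records, policy = qc_policy()) {
  if (nrow(records) == 0) return(records)
  records$pass <- TRUE
  records$fail_reason <- ""
  grp <- paste(records$plate, records$channel, sep = ":")
  for (g in unique(grp)) {
    ii <- which(grp == g)
    fs <- records$focus_score[ii]
    is_ <- records$intensity_sum[ii]
    fail <- rep("", length(ii))
    fail[records$intensity_sd[ii] == 0] <- "blank"
    thr_f <- robust_lower(fs, policy$k_mad)
    fail[fail == "" & !is.na(fs) & fs < thr_f] <- "focus"
    band <- robust_band(is_, policy$k_mad)
    fail[fail == "" & (is_ < band[1] | is_ > band[2])] <- "intensity"
    sat <- records$q99[ii] >= 1 - 1e-6 &
      records$saturated_fraction[ii] > policy$max_saturated_fraction
    fail[fail == "" & sat] <- "saturation"
    records$pass[ii] <- fail == ""
    records$fail_reason[ii] <- fail
  }
  # site-level discard
  sitekey <- paste(records$plate, records$well, records$site, sep = ":")
  bad_sites <- unique(sitekey[!records$pass])
  sib <- sitekey %in% bad_sites & records$pass
  records$pass[sib] <- FALSE
  records$fail_reason[sib] <- "sibling_channel_failed"
  records
}

robust_scale <- function(x) {
  x <- x[!is.na(x)]
  s <- stats::mad(x)
  if (s == 0) s <- stats::IQR(x) / 1.349
  s
}

robust_lower <- function(x, k) {
  stats::median(x, na.rm = TRUE) - k * robust_scale(x)
}

robust_band <- function(x, k) {
  m <- stats::median(x, na.rm = TRUE)
  s <- robust_scale(x)
  c(m - k * s, m + k * s)
}

#' QC a whole set of sites
#'
#' Convenience wrapper: computes one record per channel per site and flags
#' outliers.
#'
#' @param sites list of `image_site` objects.
#' @param policy a [qc_policy()].
#' @return flagged QC record data frame (4 rows per site).
#' @export
qc_sites <- function(sites, policy = qc_policy()) {
  recs <- do.call(rbind, lapply(sites, function(s) {
    do.call(rbind, lapply(vp_channels, function(ch) {
      compute_qc(s$channels[[ch]], plate = s$plate, well = s$well,
                 site = s$site, channel = ch)
    }))
  }))
  flag_outliers(recs, policy)
}
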