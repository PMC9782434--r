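# Shared test fixtures, all generated in code.

# a feature-table-shaped tibble of Gaussian blobs: PD rows (OFF and ON per
# patient) displaced by `sep` SDs from HC rows on every feature
make_blob_features <- function(n_pd = 6, n_hc = 5, sep = 3, seed = 7,
                               n_feat = 72, on_shift = 0) {
  set.seed(seed)
  fc <- sprintf("feat%02d", seq_len(n_feat))
  mkrow <- function(id, grp, st, mu) {
    v <- as.list(stats::rnorm(n_feat, mean = mu))
    names(v) <- fc
    dplyr::bind_cols(
      tibble::tibble(subject_id = id, group = grp, state = st),
      tibble::as_tibble(v)
    )
  }
  pd_off <- purrr::map_dfr(seq_len(n_pd),
                           ~ mkrow(sprintf("PD%02d", .x), "PD", "OFF", sep))
  pd_on <- pd_off
  pd_on$state <- "ON"
  pd_on[fc] <- pd_on[fc] + on_shift
  hc <- purrr::map_dfr(seq_len(n_hc),
                       ~ mkrow(sprintf("HC%02d", .x), "HC", "none", 0))
  dplyr::bind_rows(pd_off, pd_on, hc)
}

# a one-row subject profile with explicit kinematic parameters and no
# group bookkeeping surprises
make_profile <- function(g_pelvis = 0.7, g_trunk = 0.85, g_head = 0.9,
                         phi_pelvis = 10, phi_trunk = 8, phi_head = 5,
                         a_ml = c(18, 20, 22), a_ap = c(12, 14, 16),
                         sway_freq_ml = 0.8, sway_freq_ap = 1.0,
                         noise_accel = 0, noise_gyro = 0,
                         noise_orient = 0) {
  tibble::tibble(
    subject_id = "T01", group = "HC", state = "none",
    g_pelvis = g_pelvis, g_trunk = g_trunk, g_head = g_head,
    phi_pelvis = phi_pelvis, phi_trunk = phi_trunk, phi_head = phi_head,
    a_ml_pelvis = a_ml[1], a_ml_trunk = a_ml[2], a_ml_head = a_ml[3],
    a_ap_pelvis = a_ap[1], a_ap_trunk = a_ap[2], a_ap_head = a_ap[3],
    sway_freq_ml = sway_freq_ml, sway_freq_ap = sway_freq_ap,
    noise_accel = noise_accel, noise_gyro = noise_gyro,
    noise_orient = noise_orient
  )
}

# static sensor stream at a fixed yaw, gravity in the body frame
make_static_stream <- function(n = 500, fs = 100, yaw_deg = 0) {
  kin <- tibble::tibble(
    time_s = (seq_len(n) - 1) / fs,
    segment = "trunk",
    yaw_deg = yaw_deg,
    disp_ml_mm = 0, disp_ap_mm = 0,
    acc_ml_ms2 = 0, acc_ap_ms2 = 0
  )
  render_imu(kin)
}
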