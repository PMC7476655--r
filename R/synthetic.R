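# Synthetic fixtures with analytically known ground truth. These stand in
# for the study's (undeposited) snapshot recordings: every generator stores
# the expected value of each quantity it controls, together with the
# tolerance at which downstream operations must recover it, so the fixture
# set doubles as the pipeline's primary test harness.

# Run code under a fixed seed without disturbing the caller's RNG state.
# The generator algorithm is pinned (Mersenne-Twister / Inversion /
# Rejection) so seeded fixtures are bit-identical across platforms.
with_fixture_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
      get(".Random.seed", globalenv()) else NULL
    on.exit({
      if (is.null(old)) rm(".Random.seed", envir = globalenv())
      else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
             sample.kind = "Rejection")
  }
  force(code)
}

new_image_fixture <- function(pixels, expected, recipe, seed = NULL,
                              note = NULL) {
  structure(
    list(image = linear_gray_image(pixels), expected = expected,
         recipe = recipe, seed = seed, note = note),
    class = "image_fixture"
  )
}

#' @export
print.image_fixture <- function(x, ...) {
  cat(sprintf("<image_fixture '%s' %d x %d%s>\n", x$recipe,
              x$image$height_px, x$image$width_px,
              if (is.null(x$seed)) "" else sprintf(", seed %d", x$seed)))
  for (nm in names(x$expected))
    cat(sprintf("  expected %s = %g (tol %g)\n", nm, x$expected[[nm]]$value,
                x$expected[[nm]]$tol))
  invisible(x)
}

expected_entry <- function(value, tol) list(value = value, tol = tol)

#' Constant-luminance fixture
#'
#' Every metric of a constant image is exactly zero: no tonal spread, no
#' histogram diversity, no local structure.
#'
#' @param h,w Image dimensions (pixels).
#' @param value Constant luminance on \[0, 65535\].
#' @return An `image_fixture`; `expected` carries all five metrics at 0
#'   with tolerance 0. Fixtures smaller than the 9x9 entropy window are
#'   flagged in `note` (usable only for operations without a window
#'   precondition).
#' @export
gen_constant <- function(h, w, value) {
  if (value < 0 || value > 65535)
    vd_stop("constant value must lie on [0, 65535]", "visdemand_range_error")
  px <- matrix(as.integer(round(value)), h, w)
  note <- if (h < 9 || w < 9)
    "smaller than the 9x9 entropy window; windowed metrics will refuse it"
  new_image_fixture(
    px,
    list(contrast_pct = expected_entry(0, 0),
         global_entropy = expected_entry(0, 0),
         textured_area_pct = expected_entry(0, 0),
         highfreq_area_pct = expected_entry(0, 0),
         edge_area_pct = expected_entry(0, 0)),
    recipe = sprintf("constant(%d,%d,%d)", h, w, as.integer(value)),
    note = note
  )
}

#' Two-tone checkerboard fixture
#'
#' Square tiles of side `pitch_px` alternating between `lo` and `hi`. At
#' pitch 1 with full-range tones every 3x3 neighborhood spans the full
#' range, so the high-frequency area is exactly 100% and contrast is
#' (hi - lo)/2^16 * 100.
#'
#' @param h,w Image dimensions.
#' @param pitch_px Tile side in pixels; a pitch larger than the image
#'   degenerates to two-tone halves (still a valid fixture).
#' @param lo,hi Tone values, `lo < hi`.
#' @return An `image_fixture`. For pitch 1 the expected high-frequency area
#'   (100) and contrast are stored exactly; for larger pitches only
#'   contrast is stored (the seam-band fraction is left to the
#'   sliding-window oracle).
#' @export
gen_checkerboard <- function(h, w, pitch_px, lo = 0L, hi = 65535L) {
  stopifnot(pitch_px >= 1, lo >= 0, hi <= 65535, lo < hi)
  tile_r <- (seq_len(h) - 1L) %/% pitch_px
  tile_c <- (seq_len(w) - 1L) %/% pitch_px
  board <- outer(tile_r, tile_c, function(a, b) (a + b) %% 2L)
  px <- matrix(as.integer(ifelse(board == 0L, lo, hi)), h, w)
  n <- h * w
  k <- ceiling(0.005 * n)
  # both tones outnumber the tails whenever each appears >= k times
  expected <- list()
  n_lo <- sum(px == lo)
  if (n_lo >= k && (n - n_lo) >= k)
    expected$contrast_pct <- expected_entry((hi - lo) / 65536 * 100, 1e-9)
  if (pitch_px == 1L && (hi - lo) > 6554L)
    expected$highfreq_area_pct <- expected_entry(100, 0)
  new_image_fixture(px, expected,
                    recipe = sprintf("checkerboard(%d,%d,pitch=%d,%d,%d)",
                                     h, w, pitch_px, lo, hi))
}

#' Uniform-noise fixture
#'
#' I.i.d. uniform integers over the full 16-bit range. The tonal histogram
#' is nearly uniform over all 256 bins (global entropy close to 1) and
#' every 9x9 neighborhood is rich (textured area close to 100%).
#'
#' @param h,w Image dimensions.
#' @param seed RNG seed; identical seeds give bit-identical fixtures.
#' @return An `image_fixture` with expected `global_entropy` 1 (tol 0.01
#'   at 256x256; scaled for smaller images) and `textured_area_pct` 100
#'   (tol 0.5).
#' @export
gen_noise <- function(h, w, seed) {
  px <- with_fixture_seed(seed,
    matrix(sample.int(65536L, h * w, replace = TRUE) - 1L, h, w))
  ent_tol <- if (h * w >= 65536) 0.01 else 0.1
  new_image_fixture(
    px,
    list(global_entropy = expected_entry(1, ent_tol),
         textured_area_pct = expected_entry(100, 0.5)),
    recipe = sprintf("noise(%d,%d)", h, w), seed = seed
  )
}

#' Half-constant / half-noise fixture
#'
#' Left half a constant mid-gray, right half full-range uniform noise. The
#' textured area is 50% up to the boundary band where 9x9 windows straddle
#' the seam.
#'
#' @inheritParams gen_noise
#' @return An `image_fixture` with expected `textured_area_pct` 50,
#'   tolerance 4 percentage points (the seam band).
#' @export
gen_half_noise <- function(h, w, seed) {
  half <- w %/% 2L
  px <- with_fixture_seed(seed, {
    m <- matrix(32768L, h, w)
    m[, (half + 1L):w] <- sample.int(65536L, h * (w - half),
                                     replace = TRUE) - 1L
    m
  })
  new_image_fixture(
    px,
    list(textured_area_pct = expected_entry(100 * (w - half) / w, 4)),
    recipe = sprintf("half_noise(%d,%d)", h, w), seed = seed
  )
}

#' Horizontal-ramp fixture
#'
#' Luminance increases by `step` counts per column. Every 3x3 neighborhood
#' spans exactly `2 * step` counts (away from saturation), so for
#' `2 * step` at or below the high-frequency threshold the high-frequency
#' area is exactly 0.
#'
#' @param h,w Image dimensions.
#' @param step Per-column increment in counts; the ramp clips at 65535.
#' @return An `image_fixture`; expected `highfreq_area_pct` 0 (exact) when
#'   `2 * step <= 6554`.
#' @export
gen_ramp <- function(h, w, step) {
  stopifnot(step >= 0)
  ramp <- pmin((seq_len(w) - 1L) * step, 65535L)
  px <- matrix(as.integer(rep(ramp, each = h)), h, w)
  expected <- list()
  if (2 * step <= 6554) expected$highfreq_area_pct <- expected_entry(0, 0)
  new_image_fixture(px, expected, recipe = sprintf("ramp(%d,%d,step=%d)",
                                                   h, w, as.integer(step)))
}

#' Tail-controlled contrast fixture
#'
#' Places exactly `ceiling(0.005 * N)` pixels at `top_mean`, the same
#' number at `bottom_mean` and the remainder at their midpoint, so the
#' percentile-tail contrast is `(top_mean - bottom_mean)/2^16 * 100` by
#' construction.
#'
#' @param h,w Image dimensions.
#' @param top_mean,bottom_mean Integer tail values on \[0, 65535\] with
#'   `bottom_mean < top_mean - 1` (the midpoint must separate them).
#' @return An `image_fixture` with exact expected `contrast_pct`.
#' @export
gen_tail_controlled <- function(h, w, top_mean, bottom_mean) {
  stopifnot(top_mean == round(top_mean), bottom_mean == round(bottom_mean),
            top_mean <= 65535, bottom_mean >= 0)
  if (bottom_mean >= top_mean - 1)
    vd_stop("need bottom_mean < top_mean - 1 so a midpoint exists",
            "visdemand_range_error")
  n <- h * w
  k <- ceiling(0.005 * n)
  if (2 * k > n)
    vd_stop("image too small to hold two disjoint 0.5% tails",
            "visdemand_range_error")
  mid <- as.integer(round((top_mean + bottom_mean) / 2))
  vals <- c(rep(as.integer(top_mean), k), rep(as.integer(bottom_mean), k),
            rep(mid, n - 2L * k))
  new_image_fixture(
    matrix(vals, h, w),
    list(contrast_pct = expected_entry((top_mean - bottom_mean) / 65536 * 100,
                                       1e-9)),
    recipe = sprintf("tail_controlled(%d,%d,%d,%d)", h, w,
                     as.integer(top_mean), as.integer(bottom_mean))
  )
}

#' Scene with an embedded object of known pixel span
#'
#' A mid-gray frame of the camera's resolution with a centered white
#' rectangle spanning exactly the requested pixels; the returned
#' annotation is the embedding ground truth, so the angular-size chain can
#' be exercised end to end.
#'
#' @param cam A [camera_model()].
#' @param span_h_px,span_v_px Rectangle span in pixels (>= 1, within
#'   frame).
#' @param snapshot_id Identifier stored in the annotation.
#' @return List with `fixture` (an `image_fixture`) and `annotation` (an
#'   [object_annotation()]).
#' @export
gen_object_scene <- function(cam = camera_model(), span_h_px, span_v_px,
                             snapshot_id = "synthetic") {
  if (span_h_px < 1 || span_v_px < 1)
    vd_stop("object spans must be at least 1 pixel", "visdemand_range_error")
  if (span_h_px > cam$width_px || span_v_px > cam$height_px)
    vd_stop("object span exceeds the camera frame", "visdemand_range_error")
  px <- matrix(16384L, cam$height_px, cam$width_px)
  r0 <- (cam$height_px - span_v_px) %/% 2L
  c0 <- (cam$width_px - span_h_px) %/% 2L
  px[(r0 + 1L):(r0 + span_v_px), (c0 + 1L):(c0 + span_h_px)] <- 65535L
  fixture <- new_image_fixture(
    px, list(),
    recipe = sprintf("object_scene(%dx%d in %dx%d)", span_h_px, span_v_px,
                     cam$width_px, cam$height_px))
  list(fixture = fixture,
       annotation = object_annotation(snapshot_id, span_h_px, span_v_px))
}

# Default classifier category probabilities for the synthetic coding world.
# Stated marginal shares are used where the study reports them (75% ad hoc,
# 78% indoors, 58% home, 48% natural light, 68% within reach, 69% single
# focus plane, 17% walking, 43% coping strategy, 71% able alone, 42%/37%
# morning/afternoon); the remaining categories split the residual mass with
# plausible weights, documented in the methods vignette.
default_classifier_probs <- function() {
  list(
    duration = c("ad hoc" = 0.75, short = 0.10, medium = 0.09, long = 0.06),
    location = c(indoors = 0.78, outdoors = 0.22),
    familiarity = c(home = 0.58, public = 0.27, work = 0.10, school = 0.05),
    light_type = c(artificial = 0.32, natural = 0.48, mixed = 0.12,
                   backlit = 0.05, other = 0.03),
    brightness = c(low = 0.15, medium = 0.60, bright = 0.25),
    object_distance = c("within reach" = 0.68, short = 0.17, medium = 0.10,
                        long = 0.05),
    focus_plane = c(single = 0.69, multiple = 0.31),
    periphery = c(none = 0.40, side = 0.15, bottom = 0.30, both = 0.15),
    scanning = c(yes = 0.50, no = 0.50),
    hands = c(none = 0.40, "1 hand" = 0.35, "2 hands" = 0.25),
    walking = c(yes = 0.17, no = 0.83),
    coping_used = c(yes = 0.43, no = 0.57),
    able_alone = c(yes = 0.71, no = 0.29),
    time_of_day = c("6-12" = 0.42, "12-18" = 0.37, "18-24" = 0.16,
                    "0-6" = 0.05)
  )
}

# Default task probabilities: the published snapshot-frequency shares of
# the shipped vocabulary, renormalized to sum to 1.
default_task_probs <- function() {
  voc <- default_task_vocabulary()
  p <- voc$snapshot_pct / sum(voc$snapshot_pct)
  setNames(p, voc$task_label)
}

check_probs <- function(p, what) {
  if (is.null(names(p)) || any(!nzchar(names(p))))
    vd_stop(sprintf("%s probabilities must be named", what),
            "visdemand_validation_error")
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    vd_stop(sprintf("%s probabilities must be nonnegative and sum to 1", what),
            "visdemand_validation_error")
  p
}

#' Synthetic coding dataset with planted ground truth
#'
#' Draws task records and scene codes from known multinomial
#' distributions. Participants are assigned round-robin so every
#' participant receives records; tasks and classifier categories are
#' i.i.d. multinomial draws with the planted probabilities, which are
#' stored in the result for recovery tests.
#'
#' @param n_participants Number of participants.
#' @param n_records Number of task records / coded snapshots.
#' @param task_probs Named task probabilities summing to 1; defaults to
#'   the shipped vocabulary's published snapshot-frequency shares.
#' @param classifier_probs Named list (one entry per schema classifier) of
#'   named category probabilities; defaults to the study's reported
#'   marginal shares where stated.
#' @param seed RNG seed.
#' @return An object of class `coding_fixture`: list with `records` (task
#'   records), `codes` (scene codes) and `planted` (`task_probs`,
#'   `classifier_probs`, `seed`).
#' @export
gen_coding_dataset <- function(n_participants, n_records,
                               task_probs = default_task_probs(),
                               classifier_probs = default_classifier_probs(),
                               seed = 1L) {
  stopifnot(n_participants >= 1L, n_records >= 1L)
  task_probs <- check_probs(task_probs, "task")
  schema <- default_scene_schema()
  for (nm in names(classifier_probs)) {
    if (!nm %in% names(schema))
      vd_stop(sprintf("unknown classifier '%s' in classifier_probs", nm),
              "visdemand_validation_error")
    check_probs(classifier_probs[[nm]], nm)
    bad <- setdiff(names(classifier_probs[[nm]]), schema[[nm]]$categories)
    if (length(bad) > 0L)
      vd_stop(sprintf("classifier '%s': unknown category '%s'", nm, bad[1]),
              "visdemand_validation_error")
  }
  out <- with_fixture_seed(seed, {
    participant <- sprintf("P%02d", rep_len(seq_len(n_participants),
                                            n_records))
    snapshot <- sprintf("S%05d", seq_len(n_records))
    tasks <- sample(names(task_probs), n_records, replace = TRUE,
                    prob = task_probs)
    codes <- data.frame(snapshot_id = snapshot, stringsAsFactors = FALSE)
    for (nm in names(classifier_probs)) {
      p <- classifier_probs[[nm]]
      codes[[nm]] <- sample(names(p), n_records, replace = TRUE, prob = p)
    }
    records <- data.frame(participant_id = participant,
                          snapshot_id = snapshot, task_label = tasks,
                          stringsAsFactors = FALSE)
    list(records = records, codes = codes)
  })
  structure(
    list(records = out$records, codes = out$codes,
         planted = list(task_probs = task_probs,
                        classifier_probs = classifier_probs, seed = seed)),
    class = "coding_fixture"
  )
}

#' Synthetic dual-coder tables with a planted agreement rate
#'
#' Coder A assigns uniformly among `k_categories`; with probability
#' `agreement_rate` coder B copies A, otherwise B draws uniformly among
#' the other k-1 categories. Because disagreeing draws can never collide
#' with A's choice, the expected raw agreement equals `agreement_rate`
#' exactly; the planted expectation is stored with the fixture.
#'
#' @param n_items Number of coded items.
#' @param agreement_rate Copy probability on \[0, 1\].
#' @param k_categories Number of categories (>= 2).
#' @param seed RNG seed.
#' @return An object of class `coding_fixture`: list with `coder_a`,
#'   `coder_b` (data.frames with `snapshot_id` and a single `code`
#'   classifier column) and `planted` (`agreement_rate`,
#'   `expected_agreement_pct`, `k_categories`, `seed`).
#' @export
gen_dual_coder <- function(n_items, agreement_rate, k_categories, seed = 1L) {
  stopifnot(n_items >= 1L, agreement_rate >= 0, agreement_rate <= 1,
            k_categories >= 2L)
  cats <- sprintf("C%d", seq_len(k_categories))
  out <- with_fixture_seed(seed, {
    a <- sample(cats, n_items, replace = TRUE)
    copy <- runif(n_items) < agreement_rate
    b <- a
    if (any(!copy)) {
      # uniform among the other k-1 categories
      shift <- sample.int(k_categories - 1L, sum(!copy), replace = TRUE)
      b[!copy] <- cats[((match(a[!copy], cats) - 1L + shift) %% k_categories) + 1L]
    }
    ids <- sprintf("S%05d", seq_len(n_items))
    list(coder_a = data.frame(snapshot_id = ids, code = a,
                              stringsAsFactors = FALSE),
         coder_b = data.frame(snapshot_id = ids, code = b,
                              stringsAsFactors = FALSE))
  })
  structure(
    list(coder_a = out$coder_a, coder_b = out$coder_b,
         planted = list(agreement_rate = agreement_rate,
                        expected_agreement_pct = 100 * agreement_rate,
                        k_categories = as.integer(k_categories), seed = seed)),
    class = "coding_fixture"
  )
}

#' Write a fixture set to disk
#'
#' Emits standard formats so fixtures double as documentation examples for
#' the file-level drivers: 16-bit grayscale TIFFs for image fixtures,
#' CSVs for coding tables, and a manifest JSON with every planted ground
#' truth.
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed used for all randomized recipes.
#' @return Invisibly, the manifest list.
#' @export
write_fixture_set <- function(out_dir, seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fixtures <- list(
    constant = gen_constant(64, 64, 32768),
    checkerboard = gen_checkerboard(64, 64, 1),
    noise = gen_noise(128, 128, seed),
    half_noise = gen_half_noise(128, 128, seed + 1L),
    ramp = gen_ramp(64, 64, 10),
    tail80 = gen_tail_controlled(100, 100, 58982, 6554)
  )
  manifest <- list(seed = seed, images = list())
  for (nm in names(fixtures)) {
    fx <- fixtures[[nm]]
    fn <- paste0(nm, ".tif")
    write_gray_tiff(fx$image, file.path(out_dir, fn))
    manifest$images[[nm]] <- list(
      file = fn, recipe = fx$recipe, seed = fx$seed,
      expected = lapply(fx$expected, unclass))
  }
  coding <- gen_coding_dataset(10, 500, seed = seed + 2L)
  dual <- gen_dual_coder(1000, 0.72, 4, seed = seed + 3L)
  write.csv(coding$records, file.path(out_dir, "task_records.csv"),
            row.names = FALSE)
  write.csv(coding$codes, file.path(out_dir, "scene_codes.csv"),
            row.names = FALSE)
  write.csv(dual$coder_a, file.path(out_dir, "coder_a.csv"),
            row.names = FALSE)
  write.csv(dual$coder_b, file.path(out_dir, "coder_b.csv"),
            row.names = FALSE)
  manifest$coding <- coding$planted
  manifest$dual_coder <- dual$planted
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
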