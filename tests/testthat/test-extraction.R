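# Extraction tests run against synthetic fields whose analytic ground
# truth (paraboloid surface, film top) is attached by the generator; the
# per-offset oracle re-derives crossing heights by fine scanning along the
# probe line, independent of the threshold-crossing machinery under test.

spec_nofilm <- function(delta = 0)
  synthetic_spec(geom_smooth, cond_ref, visc_ref, phase_shift = delta)

spec_film <- function(thick = 500, top = 36)
  synthetic_spec(geom_smooth, cond_ref, visc_ref,
                 film_thickness_um = thick, film_top_height_mm = top)

# window helper mirrored here so the tests do not lean on the internal
azimuth_in_window_test <- function(az, window) {
  a <- az %% 360
  if (window[1] <= window[2]) a >= window[1] & a <= window[2]
  else a >= window[1] | a <= window[2]
}

test_that("an analytic step field is recovered to within half a z-step", {
  z_star <- 27.3
  field <- alpha_field(function(x, y, z) as.numeric(z <= z_star),
                       geom_smooth)
  cls <- extract_contact_lines(field, azimuth_step = 30,
                               offsets_um = c(50, 650))
  expect_true(all(abs(cls$contact - z_star) <= cls$z_step / 2))
  # per azimuth and offset exactly one crossing, air to water
  expect_true(all(cls$crossings$direction == "air_to_water"))
  expect_equal(nrow(cls$crossings), 12 * 2)
})

test_that("classification is invariant under monotone alpha remapping", {
  af <- generate_alpha_field(spec_nofilm())
  remap <- function(a) a^3 / (a^3 + (1 - a)^3)  # fixes 0, 0.5, 1
  af2 <- alpha_field(function(x, y, z) remap(af$fun(x, y, z)), geom_smooth)
  cls1 <- extract_contact_lines(af, azimuth_step = 15, offsets_um = 50)
  cls2 <- extract_contact_lines(af2, azimuth_step = 15, offsets_um = 50)
  expect_identical(cls1$contact, cls2$contact)
})

test_that("default grids give the expected probe count", {
  af <- generate_alpha_field(spec_nofilm())
  cls <- extract_contact_lines(af, offsets_um = 50)
  expect_gt(cls$n_samples_per_offset, 70000)
  expect_lt(cls$n_samples_per_offset, 73000)
})

test_that("extraction recovers the synthetic bulk line within one z-step", {
  for (delta in c(0, 15)) {
    af <- generate_alpha_field(spec_nofilm(delta))
    gt <- attr(af, "ground_truth")
    offs <- c(50, 450, 1050)
    cls <- extract_contact_lines(af, azimuth_step = 5, offsets_um = offs)
    for (k in seq_along(offs)) {
      for (i in seq_along(cls$azimuths)) {
        oracle <- probe_crossing_oracle(geom_smooth, gt$paraboloid, delta,
                                        cls$azimuths[i], offs[k] / 1000)
        got <- cls$contact[i, k]
        if (is.na(oracle)) {
          expect_true(is.na(got))
        } else {
          expect_lt(abs(got - oracle), cls$z_step)
        }
      }
    }
  }
})

test_that("offsets below the film read the film top, beyond it the bulk", {
  af <- suppressWarnings(generate_alpha_field(spec_film(500, 36)))
  gt <- attr(af, "ground_truth")
  cls <- extract_contact_lines(af, azimuth_step = 5)
  win <- azimuth_in_window_test(cls$azimuths, c(300, 60))
  # shallow offsets: film top everywhere in the bulk-free window
  for (k in which(cls$offsets_um <= 450)) {
    expect_true(all(abs(cls$contact[win, k] - gt$film_top_mm) < 1))
  }
  # deep offsets: the bulk crossing (where the bulk reaches at all)
  for (k in which(cls$offsets_um >= 650)) {
    for (i in which(win)) {
      oracle <- probe_crossing_oracle(geom_smooth, gt$paraboloid, 0,
                                      cls$azimuths[i],
                                      cls$offsets_um[k] / 1000)
      got <- cls$contact[i, k]
      if (is.na(oracle)) expect_true(is.na(got))
      else expect_lt(abs(got - oracle), cls$z_step)
    }
  }
})

test_that("film thickness bracketing lands on the neighbouring offsets", {
  af <- suppressWarnings(generate_alpha_field(spec_film(500, 36)))
  cls <- extract_contact_lines(af, azimuth_step = 5)
  est <- estimate_film_thickness(cls)
  expect_equal(est$lower_um, 450)
  expect_equal(est$upper_um, 650)
  expect_lt(abs(est$film_top_mm - 36), 1)
})

test_that("no film yields the zero bracket, a thick film saturates", {
  cls0 <- extract_contact_lines(generate_alpha_field(spec_nofilm()),
                                azimuth_step = 5)
  est0 <- estimate_film_thickness(cls0)
  expect_equal(est0$lower_um, 0)
  expect_equal(est0$upper_um, 50)
  af_thick <- generate_alpha_field(spec_film(1500, 36))
  cls_t <- extract_contact_lines(af_thick, azimuth_step = 5)
  est_t <- estimate_film_thickness(cls_t)
  expect_equal(est_t$lower_um, 1050)
  expect_true(is.infinite(est_t$upper_um))
})

test_that("the apex shift reports the generator's phase shift", {
  for (delta in c(0, 15, 30, -30)) {
    af <- generate_alpha_field(spec_nofilm(delta))
    cls <- extract_contact_lines(af, offsets_um = 50)
    expect_lt(abs(apex_shift(cls) - delta), cls$azimuth_step + 1e-9)
  }
})

test_that("a flat line has no defined apex", {
  field <- alpha_field(function(x, y, z) as.numeric(z <= 20), geom_smooth)
  cls <- extract_contact_lines(field, azimuth_step = 30, offsets_um = 50)
  expect_error(apex_shift(cls), "degenerate")
})

test_that("crossings alternate and descend within each probe line", {
  af <- suppressWarnings(generate_alpha_field(spec_film(500, 36)))
  cls <- extract_contact_lines(af, azimuth_step = 15)
  by_line <- split(cls$crossings,
                   list(cls$crossings$offset_um, cls$crossings$azimuth),
                   drop = TRUE)
  for (sub in by_line) {
    expect_true(all(diff(sub$height) < 0))
    expect_equal(sub$direction,
                 rep(c("air_to_water", "water_to_air"),
                     length.out = nrow(sub)))
  }
})

test_that("out-of-support samples are read as air and counted", {
  sampler <- function(x, y, z) ifelse(z > 50, NA_real_, as.numeric(z <= 20))
  cls <- extract_contact_lines(alpha_field(sampler, geom_smooth),
                               azimuth_step = 90, offsets_um = 50)
  expect_gt(cls$n_outside_support, 0)
  expect_true(all(abs(cls$contact - 20) <= cls$z_step / 2))
})
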