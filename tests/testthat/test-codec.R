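test_that("known scaffold codes validate and the C11 scale is shifted", {
  g <- iridoid_grammar()
  cat <- catalpol_code()
  expect_true(validate_code(cat, g)$valid)
  expect_equal(unname(cat$re["C11"]), 3)     # fully decarboxylated C11
  expect_true(validate_code(scaffold_code(rep(0L, 10)), g)$valid)
  expect_true(validate_code(aucubin_code(), g)$valid)
  expect_true(validate_code(bartsioside_code(), g)$valid)
})

test_that("unpaired or misplaced unsaturation flags are rejected", {
  g <- iridoid_grammar()
  lone <- scaffold_code(rep(0L, 10),
                        im = c(0, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  v <- validate_code(lone, g)
  expect_false(v$valid)
  expect_match(paste(v$violations, collapse = " "), "pair")
  # flags on non-adjacent carbons do not pair either
  apart <- scaffold_code(rep(0L, 10),
                         im = c(1, 0, 0, 0, 0, 0, 0, 0, 1, 0))
  expect_false(validate_code(apart, g)$valid)
  # epoxide restricted to its configured bond
  bad_epo <- scaffold_code(rep(0L, 10),
                           im = c(0, 3, 3, 0, 0, 0, 0, 0, 0, 0))
  expect_false(validate_code(bad_epo, g)$valid)
  # out-of-range oxidation state names the carbon
  high <- scaffold_code(c(9, rep(0L, 9)))
  v2 <- validate_code(high, g)
  expect_false(v2$valid)
  expect_match(v2$violations[1], "C1")
  # malformed position sets are a structural error, not a violation list
  expect_error(scaffold_code(1:3), "position")
})

test_that("serialization round-trips and uses the fourths notation", {
  g <- iridoid_grammar()
  txt <- format_code(catalpol_code())
  expect_match(txt, "3/4i")
  expect_match(txt, "1/4i")
  expect_equal(parse_code(txt), catalpol_code())
  sp <- toy_space()
  for (k in sample(sp$keys, 50)) {
    expect_equal(format_code(parse_code(k)), k)
  }
  expect_error(parse_code("1,2,3"), "10 tokens")
  expect_error(parse_code(paste(c("x", rep("0", 9)), collapse = ",")),
               "C1.*malformed|malformed token")
})

test_that("generalized distance: identity, symmetry, unit moves, calibration", {
  g <- iridoid_grammar()
  a <- scaffold_code(rep(0L, 10))
  expect_equal(generalized_distance(a, a, g), 0)
  # one hydroxylation apart
  b <- scaffold_code(c(1, rep(0L, 9)))
  expect_equal(generalized_distance(a, b, g), 1)
  expect_equal(generalized_distance(b, a, g), 1)
  # literal complex arithmetic gives 0.5 for a desaturation pair,
  # calibration restores the unit reaction distance
  d <- scaffold_code(rep(0L, 10), im = c(0, 1, 1, 0, 0, 0, 0, 0, 0, 0))
  expect_equal(generalized_distance(a, d, g, calibrate = FALSE), 0.5)
  expect_equal(generalized_distance(a, d, g), 1)
  # epoxidation from the double bond is 1 under both conventions
  au <- aucubin_code(); cat <- catalpol_code()
  expect_equal(generalized_distance(au, cat, g, calibrate = FALSE), 1)
  expect_equal(generalized_distance(au, cat, g), 1)
})

test_that("every applicable move changes the calibrated distance by exactly 1", {
  g <- iridoid_grammar()
  sp <- default_space()
  codes <- random_codes(sp, 120, seed = 42)
  for (code in codes) {
    mv <- list_moves(code, g)
    for (m in mv) {
      out <- apply_move(code, m, g)
      expect_true(validate_code(out, g)$valid)
      expect_equal(generalized_distance(code, out, g), 1,
                   info = paste(m$kind, format_code(code)))
    }
  }
})

test_that("list_moves equals a brute-force applicability scan", {
  g <- iridoid_grammar()
  # brute force: try every (kind, carbon/bond) combination via apply_move
  brute <- function(code) {
    res <- character(0)
    for (j in seq_along(g$carbons)) {
      m <- iridograph:::.move(iridograph:::.ox_kind(g$carbons[j],
                                                    code$re[[j]]),
                              g$carbons[j])
      out <- try(apply_move(code, m, g), silent = TRUE)
      if (!inherits(out, "try-error")) res <- c(res, format_code(out))
    }
    for (b in seq_len(nrow(g$bonds))) {
      for (kind in c("desaturation", "epoxidation")) {
        m <- iridograph:::.move(kind, g$carbons[g$bonds[b, ]], detail = b)
        out <- try(apply_move(code, m, g), silent = TRUE)
        if (!inherits(out, "try-error")) res <- c(res, format_code(out))
      }
      for (b2 in seq_len(nrow(g$bonds))) {
        if (b2 == b) next
        kind <- if (length(intersect(g$bonds[b, ], g$bonds[b2, ])) == 1)
          "migration" else "relocation"
        if (!kind %in% g$moves) next
        m <- iridograph:::.move(kind, g$carbons[g$bonds[b2, ]],
                                detail = c(b, b2))
        out <- try(apply_move(code, m, g), silent = TRUE)
        if (!inherits(out, "try-error")) res <- c(res, format_code(out))
      }
      if ("double_desaturation" %in% g$moves && b < nrow(g$bonds)) {
        for (b2 in (b + 1):nrow(g$bonds)) {
          if (any(g$bonds[b2, ] %in% g$bonds[b, ])) next
          m <- iridograph:::.move("double_desaturation",
                                  g$carbons[c(g$bonds[b, ], g$bonds[b2, ])],
                                  detail = c(b, b2))
          out <- try(apply_move(code, m, g), silent = TRUE)
          if (!inherits(out, "try-error")) res <- c(res, format_code(out))
        }
      }
    }
    sort(unique(res))
  }
  sp <- default_space()
  zero <- scaffold_code(rep(0L, 10))
  for (code in c(list(zero), random_codes(sp, 15, seed = 7))) {
    got <- sort(unique(vapply(list_moves(code, g), function(m)
      format_code(apply_move(code, m, g)), character(1))))
    expect_equal(got, brute(code), info = format_code(code))
  }
})

test_that("oxidation beyond the state bound is rejected with a reason", {
  g <- iridoid_grammar()
  top <- scaffold_code(c(g$n_states - 1L))
  m <- iridograph:::.move("decarboxylation", "C10")
  expect_error(apply_move(top, m, g), "cannot oxidize")
  # C11 direct oxidation walks aldehyde -> acid without an alcohol step
  c11_1 <- scaffold_code(c(rep(0L, 9), 1L))
  m11 <- iridograph:::.move("C11-direct-oxidation", "C11")
  out <- apply_move(c11_1, m11, g)
  expect_equal(unname(out$re["C11"]), 2)
})

test_that("a terminal highly oxidized code has fewer forward moves than zero", {
  g <- iridoid_grammar()
  zero <- scaffold_code(rep(0L, 10))
  top <- scaffold_code(g$n_states - 1L)
  expect_true(validate_code(top, g)$valid)
  expect_lt(length(list_moves(top, g)), length(list_moves(zero, g)))
})
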