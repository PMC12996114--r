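test_that("validation enforces the schema and value invariants", {
  p <- tiny_panel()
  expect_silent(validate_sessions(p))

  expect_error(validate_sessions(p[setdiff(names(p), "speed_max")]),
               class = "workloadcast_schema_error")

  neg <- p; neg$distance_total[2] <- -5
  expect_error(validate_sessions(neg), class = "workloadcast_validation_error")
  expect_error(validate_sessions(neg), "distance_total")

  dup <- dplyr::bind_rows(p, p[1, ])
  expect_error(validate_sessions(dup), class = "workloadcast_validation_error")

  bad_pos <- p; bad_pos$position[1] <- "goalkeeper"
  expect_error(validate_sessions(bad_pos), class = "workloadcast_validation_error")

  bad_type <- p; bad_type$session_type[1] <- "friendly"
  expect_error(validate_sessions(bad_type), class = "workloadcast_validation_error")

  two_pos <- p; two_pos$position[2] <- "back"
  expect_error(validate_sessions(two_pos), class = "workloadcast_validation_error")

  inf_val <- p; inf_val$jumps[1] <- Inf
  expect_error(validate_sessions(inf_val), class = "workloadcast_validation_error")
})

test_that("CSV round trips are lossless and byte-stable", {
  p <- tiny_panel()
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")

  write_sessions(p, f1)
  back <- read_sessions(f1)
  expect_equal(nrow(back), nrow(p))
  expect_equal(back, validate_sessions(p))

  # two writes of the same panel are byte-identical
  write_sessions(back, f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))

  # write(read(f)) equals the canonicalised file byte-for-byte
  f3 <- withr::local_tempfile(fileext = ".csv")
  write_sessions(read_sessions(f1), f3)
  expect_identical(readLines(f1), readLines(f3))

  # header line is canonical
  expect_identical(readLines(f1)[1], paste(session_columns(), collapse = ","))
})

test_that("round trip is the identity on generated panels (property)", {
  for (s in 1:3) {
    panel <- small_sim_panel(seed = s, n_sessions = 12)$sessions
    # CSV carries one decimal place; round first so identity is exact
    panel <- dplyr::mutate(panel,
                           dplyr::across(dplyr::all_of(kpi_names()),
                                         ~ round(.x, 1)))
    f <- withr::local_tempfile(fileext = ".csv")
    write_sessions(panel, f)
    expect_equal(read_sessions(f), validate_sessions(panel))
  }
})

test_that("an empty panel writes a header-only file", {
  f <- withr::local_tempfile(fileext = ".csv")
  write_sessions(tiny_panel()[0, ], f)
  expect_identical(readLines(f), paste(session_columns(), collapse = ","))
})

test_that("reading a file with a negative KPI fails with a named row", {
  f <- withr::local_tempfile(fileext = ".csv")
  p <- tiny_panel(); write_sessions(p, f)
  lines <- sub("5000.0", "-5.0", readLines(f), fixed = TRUE)
  writeLines(lines, f)
  expect_error(read_sessions(f), class = "workloadcast_validation_error")
})

test_that("position summary matches hand-computed means", {
  s <- summarize_by_position(tiny_panel())
  wing <- s[s$position == "wing", ]
  expect_equal(wing$distance_total, mean(c(5000, 6000, 5200)))
  expect_equal(wing$n_sessions, 3L)
  back <- s[s$position == "back", ]
  expect_equal(back$distance_total, 4400)
  # team total is session-weighted: mean over all four records
  total <- s[s$position == "team_total", ]
  expect_equal(total$distance_total, mean(c(5000, 6000, 5200, 4400)))
  expect_false(isTRUE(all.equal(total$distance_total,
                                mean(c(wing$distance_total, 4400)))))
})

test_that("a panel of constant wing sessions reproduces the configured mean", {
  p <- tiny_panel()[c(1, 3), ]
  p$distance_total <- 5294.5
  s <- summarize_by_position(p)
  expect_equal(s$distance_total[s$position == "wing"], 5294.5)
})

test_that("single-record summary equals that record's KPIs", {
  p <- tiny_panel()[4, ]
  s <- summarize_by_position(p)
  expect_equal(s$metabolic_power_max[s$position == "back"], 8100)
  expect_equal(nrow(s), 2) # back + team_total
})

test_that("summary is permutation invariant and means are bounded", {
  panel <- small_sim_panel(seed = 5, n_sessions = 15)$sessions
  s1 <- summarize_by_position(panel)
  set.seed(1)
  s2 <- summarize_by_position(panel[sample.int(nrow(panel)), ])
  expect_equal(s1, s2)
  for (pos in unique(panel$position)) {
    sub <- panel[panel$position == pos, ]
    for (k in kpi_names()) {
      m <- s1[[k]][s1$position == pos]
      expect_gte(m, min(sub[[k]]))
      expect_lte(m, max(sub[[k]]))
    }
  }
  expect_error(summarize_by_position(tiny_panel()[0, ]),
               class = "workloadcast_empty_error")
})
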