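test_that("necklace counts match the ring-state references", {
  t0 <- Sys.time()
  expect_equal(necklace_count(6, 4), 700)
  expect_equal(necklace_count(6, 20), 10668140)
  expect_lt(as.numeric(Sys.time() - t0, units = "secs"), 1)
  expect_equal(necklace_count(1, 7), 7)
  expect_error(necklace_count(0, 2))
  expect_error(necklace_count(3, -1))
})

test_that("enumeration agrees with the counting formula", {
  expect_equal(enumerate_ring_species(2, 2), c("00", "01", "11"))
  expect_equal(length(enumerate_ring_species(6, 4)), 700)
  expect_equal(length(enumerate_ring_species(5, 3)), necklace_count(5, 3))
  # brute-force reference for (3, 2): strings modulo rotation
  expect_equal(necklace_count(3, 2), 4)
  expect_equal(length(enumerate_ring_species(3, 2)), 4)
  for (n in 2:8) for (k in 2:4) {
    if (k^n > 1e6) next
    expect_equal(length(enumerate_ring_species(n, k)), necklace_count(n, k),
                 info = sprintf("n=%d k=%d", n, k))
  }
  expect_error(enumerate_ring_species(30, 3), "guard")
})
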