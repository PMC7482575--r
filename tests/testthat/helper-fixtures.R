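# shared toy instances; everything is generated in code
fx <- make_fixtures(seed = 42L)

# compare two degree sequences by value (ignoring solver attributes)
expect_same_histogram <- function(a, b) {
  expect_identical(stats::setNames(as.integer(a), names(a)),
                   stats::setNames(as.integer(b), names(b)))
}

stub_total <- function(seq) sum(as.integer(names(seq)) * as.integer(seq))
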