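# Conference matrices C of order n (zero diagonal, +/-1 off-diagonal,
# C'C = (n-1) I), the generating cores of definitive screening designs.
# Orders 6, 10 and 14 are Paley constructions over GF(5), GF(9) and GF(13);
# orders 4, 8 and 12 are skew-type. Verified numerically in the test suite.
conference_matrices <- list(
  "4" = matrix(c(0, -1, -1, -1, -1, 0, 1, -1, -1, -1, 0, 1, -1, 1, -1, 0), nrow = 4),
  "6" = matrix(c(0, 1, 1, 1, 1, 1, 1, 0, 1, -1, -1, 1, 1, 1, 0, 1, -1, -1, 1, -1, 1, 0, 1, -1, 1, -1, -1, 1, 0, 1, 1, 1, -1, -1, 1, 0), nrow = 6),
  "8" = matrix(c(0, -1, -1, -1, -1, -1, -1, -1, 1, 0, 1, 1, -1, 1, -1, -1, 1, -1, 0, 1, 1, -1, 1, -1, 1, -1, -1, 0, 1, 1, -1, 1, 1, 1, -1, -1, 0, 1, 1, -1, 1, -1, 1, -1, -1, 0, 1, 1, 1, 1, -1, 1, -1, -1, 0, 1, 1, 1, 1, -1, 1, -1, -1, 0), nrow = 8),
  "10" = matrix(c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 1, 1, 1, -1, -1, 1, -1, -1, 1, 1, 0, 1, -1, 1, -1, -1, 1, -1, 1, 1, 1, 0, -1, -1, 1, -1, -1, 1, 1, 1, -1, -1, 0, 1, 1, 1, -1, -1, 1, -1, 1, -1, 1, 0, 1, -1, 1, -1, 1, -1, -1, 1, 1, 1, 0, -1, -1, 1, 1, 1, -1, -1, 1, -1, -1, 0, 1, 1, 1, -1, 1, -1, -1, 1, -1, 1, 0, 1, 1, -1, -1, 1, -1, -1, 1, 1, 1, 0), nrow = 10),
  "12" = matrix(c(0, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, -1, 1, 0, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1, 1, -1, 0, 1, -1, 1, 1, 1, -1, -1, -1, 1, 1, 1, -1, 0, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1, 1, -1, 0, 1, -1, 1, 1, 1, -1, -1, 1, -1, -1, 1, -1, 0, 1, -1, 1, 1, 1, -1, 1, -1, -1, -1, 1, -1, 0, 1, -1, 1, 1, 1, 1, 1, -1, -1, -1, 1, -1, 0, 1, -1, 1, 1, 1, 1, 1, -1, -1, -1, 1, -1, 0, 1, -1, 1, 1, 1, 1, 1, -1, -1, -1, 1, -1, 0, 1, -1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1, 0, 1, 1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1, 0), nrow = 12),
  "14" = matrix(c(0, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 1, 0, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 1, 1, 0, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, -1, 1, -1, 1, 0, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, 1, 1, -1, 1, 0, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, 1, 1, -1, 1, 0, 1, -1, 1, 1, -1, -1, -1, -1, 1, -1, 1, 1, -1, 1, 0, 1, -1, 1, 1, -1, -1, -1, 1, -1, -1, 1, 1, -1, 1, 0, 1, -1, 1, 1, -1, -1, 1, -1, -1, -1, 1, 1, -1, 1, 0, 1, -1, 1, 1, -1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 0, 1, -1, 1, 1, 1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 0, 1, -1, 1, 1, 1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 0, 1, -1, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 0, 1, 1, 1, -1, 1, 1, -1, -1, -1, -1, 1, 1, -1, 1, 0), nrow = 14)
)

# Standard 12-run Plackett-Burman generator row (cyclic) plus all-minus row.
pb12_first_row <- c(1, 1, -1, 1, 1, 1, -1, -1, -1, 1, -1)
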