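# Shared fixtures built in code.

# Random coupled two-site model with microscopic constants in a sane range.
random_coupled_model <- function() {
  pa <- runif(1, 3, 9)
  pb <- runif(1, 3, 9)
  shift <- runif(1, 0.5, 3) # coupling raises the second ionization
  coupled_site_model(pa, pb, pk_b_given_a = pb + shift)
}

# Independent quadratic scan for C..C motifs (oracle for find_cxxc).
brute_force_cxxc <- function(seq) {
  letters <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(letters)
  hits <- integer(0)
  if (n >= 4L) {
    for (i in seq_len(n - 3L)) {
      if (letters[i] == "C" && letters[i + 3L] == "C") {
        hits <- c(hits, i - 1L)
      }
    }
  }
  hits
}

aa_alphabet <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
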