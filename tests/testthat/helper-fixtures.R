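# Shared fixture builders for the unit tests.

rand_seq <- function(n, gc = 0.5) {
  editscan:::random_dna(n, gc)
}

# a fixed 19-nt guide used across tests (arbitrary but frozen)
test_guide <- function(name = "gX",
                       protospacer = "GTCACTTACTCGTCATCCA", ...) {
  guide_target(name, protospacer, ...)
}

# implant `site` into `host` at 0-based position `at`
implant_at <- function(host, site, at) {
  paste0(substr(host, 1, at), site,
         substr(host, at + nchar(site) + 1, nchar(host)))
}

# mutate k protospacer positions (returns the mutated protospacer)
mutate_proto <- function(proto, k, positions = NULL) {
  chars <- strsplit(proto, "")[[1]]
  if (is.null(positions)) positions <- sample(length(chars), k)
  for (p in positions) {
    chars[p] <- setdiff(c("A", "C", "G", "T"), chars[p])[1]
  }
  paste(chars, collapse = "")
}

# shared amplicon fixture: 90 nt flanks around protospacer + TGG
mk_amplicon <- function(seed = 61, left = 90, right = 90) {
  set.seed(seed)
  g <- test_guide("gA")
  amp <- paste0(rand_seq(left), g$protospacer, "TGG", rand_seq(right))
  amplicon_spec("site1", amp, g)
}

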