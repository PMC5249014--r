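# Package-wide constants; file name keeps them first in the collate
# order because later files compute on them at load time.

NT_ALPHABET <- c("A", "C", "G", "U")

# first nucleotide major: AA, AC, AG, AU, CA, ...
DINUCS <- paste0(rep(NT_ALPHABET, each = 4L), rep(NT_ALPHABET, times = 4L))

TRIPLET_PATTERNS <- apply(expand.grid(p3 = c("u", "p"), p2 = c("u", "p"),
                                      p1 = c("u", "p"))[, 3:1], 1L,
                          paste, collapse = "")

TRIPLET_NAMES <- as.vector(t(outer(NT_ALPHABET, TRIPLET_PATTERNS,
                                   function(nt, p) paste0("tri_", nt, "_", p))))
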