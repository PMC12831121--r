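## Package-wide registry for pluggable components (denoisers, segmentation
## backends). Defined first in collation order; built-ins register at
## source time from their own files.
.microseg_registry <- new.env(parent = emptyenv())
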