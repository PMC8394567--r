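# data.table non-standard-evaluation column names
utils::globalVariables(c("animal_id", "timestamp", "date", "lat", "lon",
                         "n_fixes", ".N", "."))
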