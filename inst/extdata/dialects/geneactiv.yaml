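device: "GENEActiv"
manufacturer: "Activeinsights"
delimiter: ","
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["timestamp"]
  format: "%Y-%m-%d %H:%M:%S"
  timezone: supplied
id_column: null
channels:
  - column: "light"
    channel: "lux"
    unit: "lx"
requires_preprocessing: true
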