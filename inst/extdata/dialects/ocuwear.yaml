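device: "OcuWEAR"
manufacturer: "Ocutune"
delimiter: ","
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["Timestamp"]
  format: "%Y-%m-%d %H:%M:%S"
  timezone: supplied
id_column: null
channels:
  - column: "Melanopic EDI"
    channel: "MEDI"
    unit: "mel-EDI lx"
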