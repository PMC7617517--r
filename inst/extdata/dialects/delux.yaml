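device: "DeLux"
manufacturer: "Intelligent Automation Inc."
delimiter: ","
skip: 0
header: true
decimal_mark: "."
datetime:
  columns: ["Timestamp"]
  format: "%Y-%m-%dT%H:%M:%S"
  timezone: supplied
id_column: "DeviceID"
channels:
  - column: "mEDI"
    channel: "MEDI"
    unit: "mel-EDI lx"
  - column: "Photopic"
    channel: "lux"
    unit: "lx"
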