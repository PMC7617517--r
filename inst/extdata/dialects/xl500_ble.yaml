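device: "XL-500 BLE"
manufacturer: "NanoLambda"
delimiter: ","
skip: 0
header: false
decimal_mark: "."
datetime:
  columns: [1]
  format: "%Y-%m-%d %H:%M:%S"
  timezone: supplied
id_column: null
channels:
  - column: 2
    channel: "lux"
    unit: "lx"
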