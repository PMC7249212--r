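{
  "comment": "Order-of-magnitude maximum rate-of-spread (m/h) per Anderson fuel class at zero humidity. Grass groups (1-3) spread fastest, shrub groups (4-7) intermediate, timber litter (8-10) slow, slash (11-13) slow-to-intermediate. Replace with locally calibrated rates for operational use.",
  "ros_max_by_fuel": {
    "1": 1500,
    "2": 1000,
    "3": 2000,
    "4": 1200,
    "5": 600,
    "6": 800,
    "7": 500,
    "8": 150,
    "9": 250,
    "10": 300,
    "11": 200,
    "12": 250,
    "13": 300
  },
  "humidity_damping": 3,
  "wind_saturation_speed": 30000,
  "slope_coefficient": 2
}
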