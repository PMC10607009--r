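{
  "type": "FeatureCollection",
  "note": "Coarse hand-simplified source-area outlines (synthetic approximations, <= 20 vertices each); supply precise boundaries for operational use.",
  "features": [
    {
      "type": "Feature",
      "properties": {"name": "Zhejiang", "abbrev": "ZJ"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [118.4, 28.3], [118.0, 29.2], [119.2, 31.0], [120.7, 30.9],
        [122.0, 30.2], [121.9, 29.2], [121.0, 27.8], [120.4, 27.1],
        [119.6, 27.4], [118.7, 27.6], [118.4, 28.3]
      ]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "Fujian", "abbrev": "FJ"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [115.9, 25.0], [116.5, 26.4], [117.1, 27.3], [118.3, 28.0],
        [119.5, 27.7], [120.4, 27.1], [119.9, 26.0], [119.6, 25.3],
        [118.1, 24.3], [117.2, 23.6], [116.5, 24.6], [115.9, 25.0]
      ]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "Guangdong", "abbrev": "GD"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [109.7, 21.5], [110.5, 20.3], [111.0, 21.5], [112.0, 21.8],
        [113.0, 22.0], [114.5, 22.4], [115.5, 22.7], [116.8, 23.2],
        [117.2, 23.6], [116.5, 24.6], [115.0, 25.0], [113.8, 25.3],
        [112.0, 25.2], [111.0, 24.5], [110.0, 23.0], [109.7, 21.5]
      ]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "Jiangxi", "abbrev": "JX"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [113.9, 25.0], [114.2, 26.5], [113.8, 27.5], [114.3, 28.7],
        [115.0, 29.7], [116.2, 29.9], [117.0, 29.6], [118.0, 29.0],
        [118.4, 28.3], [117.8, 27.0], [117.0, 26.0], [116.0, 25.0],
        [115.0, 24.6], [113.9, 25.0]
      ]]}
    },
    {
      "type": "Feature",
      "properties": {"name": "Taiwan", "abbrev": "TW"},
      "geometry": {"type": "Polygon", "coordinates": [[
        [120.1, 23.0], [120.2, 23.8], [121.0, 25.0], [121.6, 25.3],
        [122.0, 25.0], [121.6, 24.0], [121.0, 22.9], [120.7, 22.0],
        [120.3, 22.4], [120.1, 23.0]
      ]]}
    }
  ]
}
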