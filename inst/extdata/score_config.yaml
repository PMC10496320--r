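version: '1.0'
dash:
  levels_kcal:
  - 1600.0
  - 2000.0
  - 2600.0
  - 3100.0
  components:
    fruit:
      max_points: 10.0
      direction: forward
      groups: fruit
      targets:
        '1600': 4.0
        '2000': 4.5
        '2600': 5.5
        '3100': 6.0
    vegetable:
      max_points: 10.0
      direction: forward
      groups: vegetable
      targets:
        '1600': 3.5
        '2000': 4.5
        '2600': 5.5
        '3100': 6.0
    meat_poultry_fish_egg:
      max_points: 10.0
      direction: reverse
      groups:
      - red_meat
      - processed_meat
      - poultry
      - fish
      - egg
      targets:
        '1600': 1.5
        '2000': 2.0
        '2600': 2.0
        '3100': 2.5
    nuts_seeds_legumes:
      max_points: 10.0
      direction: forward
      groups:
      - nut_seed
      - legume
      targets:
        '1600': 0.428571428571
        '2000': 0.642857142857
        '2600': 1.0
        '3100': 1.0
    fats_oils:
      max_points: 10.0
      direction: reverse
      groups:
      - oil_olive
      - oil_other
      - butter
      targets:
        '1600': 2.0
        '2000': 2.5
        '2600': 3.0
        '3100': 4.0
    sweets:
      max_points: 10.0
      direction: reverse
      groups: sweets
      targets:
        '1600': 0.0
        '2000': 0.714285714286
        '2600': 0.285714285714
        '3100': 2.0
    dairy_total:
      max_points: 5.0
      direction: forward
      groups: dairy
      targets:
        '1600': 2.5
        '2000': 2.5
        '2600': 3.0
        '3100': 3.5
    dairy_lowfat:
      max_points: 5.0
      type: share
      numerator: dairy_lowfat
      denominator: dairy
      target_share: 0.75
    whole_grain:
      max_points: 5.0
      direction: forward
      groups: wholegrain
      targets:
        '1600': 3.0
        '2000': 4.0
        '2600': 5.5
        '3100': 6.5
    high_fibre_grain:
      max_points: 5.0
      direction: forward
      groups: high_fibre_grain
      targets:
        '1600': 3.0
        '2000': 4.0
        '2600': 5.5
        '3100': 6.5
vegetarian:
  reference_kj: 8368.0
  diet_components:
    whole_grain:
      direction: forward
      groups: wholegrain
      full: 5.0
      half: 2.5
    legume_soy:
      direction: forward
      groups:
      - legume
      - soy
      full: 1.0
      half: 0.5
    vegetable:
      direction: forward
      groups: vegetable
      full: 6.0
      half: 3.0
    fruit:
      direction: forward
      groups: fruit
      full: 3.0
      half: 1.5
    nut_seed:
      direction: forward
      groups: nut_seed
      full: 1.0
      half: 0.5
    vegetable_oil:
      direction: forward
      groups:
      - oil_olive
      - oil_other
      full: 2.0
      half: 1.0
    dairy:
      direction: reverse
      groups: dairy
      full: 2.0
      half: 4.0
    egg:
      direction: reverse
      groups: egg
      full: 0.5
      half: 1.0
    sweets:
      direction: reverse
      groups: sweets
      full: 1.0
      half: 2.0
    flesh_food:
      direction: reverse
      groups:
      - red_meat
      - processed_meat
      - poultry
      - fish
      full: 0.0
      half: 0.5
  exercise:
    full_category: 2.0
    half_category: 1.0
  water:
    full: 0.5
    half: 0.25
  sunlight_default: 1.0
heifa:
  vegetable:
    quantity_max: 5.0
    target: 5.0
    variety_max: 5.0
    variety_target: 5.0
  fruit:
    quantity_max: 5.0
    target: 2.0
    variety_max: 5.0
    variety_target: 2.0
  grain:
    quantity_max: 5.0
    target: 6.0
    groups:
    - wholegrain
    - refined_grain
    wholegrain_max: 5.0
    wholegrain_share: 0.5
  dairy:
    max_points: 10.0
    target: 2.5
    groups: dairy
  meat_alternatives:
    max_points: 10.0
    target: 2.5
    groups:
    - red_meat
    - poultry
    - fish
    - egg
    - legume
    - nut_seed
  discretionary:
    max_points: 10.0
    full_at: 2.5
    zero_at: 6.0
    groups: discretionary
  sat_fat:
    max_points: 10.0
    full_at_pct: 10.0
    zero_at_pct: 15.0
  added_sugar:
    max_points: 10.0
    full_at_pct: 15.0
    zero_at_pct: 20.0
  sodium:
    max_points: 10.0
    full_at_mg: 2000.0
    zero_at_mg: 3600.0
  water:
    max_points: 5.0
    full_fraction: 0.5
  alcohol:
    max_points: 5.0
    limit_serves: 2.0
    groups: alcohol
medas:
  criteria:
    olive_oil_main_fat:
      op: 'true'
    olive_oil_tbsp_day:
      op: ge
      threshold: 4.0
    vegetable_serves_day:
      op: ge
      threshold: 2.0
    fruit_serves_day:
      op: ge
      threshold: 3.0
    red_processed_meat_serves_day:
      op: lt
      threshold: 1.0
    butter_serves_day:
      op: lt
      threshold: 1.0
    ssb_serves_day:
      op: lt
      threshold: 1.0
    wine_glasses_week:
      op: ge
      threshold: 7.0
    legume_serves_week:
      op: ge
      threshold: 3.0
    fish_serves_week:
      op: ge
      threshold: 3.0
    sweets_serves_week:
      op: lt
      threshold: 3.0
    nut_serves_week:
      op: ge
      threshold: 3.0
    white_meat_preference:
      op: 'true'
    sofrito_per_week:
      op: ge
      threshold: 2.0
ermeddiet:
  criteria:
    olive_oil_main_fat:
      op: 'true'
    vegetable_serves_day:
      op: ge
      threshold: 2.0
    fruit_serves_day:
      op: ge
      threshold: 3.0
    red_processed_meat_serves_day:
      op: lt
      threshold: 1.0
    butter_serves_day:
      op: lt
      threshold: 1.0
    ssb_serves_day:
      op: lt
      threshold: 1.0
    wine_glasses_week:
      op: ge
      threshold: 7.0
    legume_serves_week:
      op: ge
      threshold: 3.0
    fish_serves_week:
      op: ge
      threshold: 3.0
    sweets_serves_week:
      op: lt
      threshold: 3.0
    nut_serves_week:
      op: ge
      threshold: 3.0
    white_meat_preference:
      op: 'true'
    sofrito_per_week:
      op: ge
      threshold: 2.0
    whole_grain_serves_day:
      op: ge
      threshold: 1.0
    white_bread_serves_day:
      op: lt
      threshold: 1.0
    refined_grain_serves_week:
      op: lt
      threshold: 2.0
    added_sugar_in_drinks:
      op: 'false'
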