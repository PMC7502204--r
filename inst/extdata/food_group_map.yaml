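# Food item -> food group map (26 groups).
# Representative items per group; replace with a study-specific catalogue
# via read_food_group_map() for real recall data.
rice:
  - boiled_rice
  - rice_porridge
wheat:
  - steamed_bun
  - noodles
  - wheat_bran
refined_grains:
  - white_bread
  - pizza
  - muffin
  - pancake
other_cereals:
  - corn
  - millet
  - sorghum
fried_foods:
  - fried_dough_stick
  - fried_rice
nuts_legumes:
  - peanuts
  - walnuts
  - tofu
  - soybeans
roots_tubers:
  - potato
  - sweet_potato
  - taro
deep_color_vegetables:
  - spinach
  - carrot
  - tomato
light_color_vegetables:
  - cabbage
  - cucumber
  - winter_melon
fungi_algae:
  - mushroom
  - agaric
  - kelp
  - seaweed
pickled_vegetables:
  - pickled_mustard_root
  - pickled_radish
fruits:
  - apple
  - banana
  - orange
pork:
  - pork_lean
  - pork_belly
poultry:
  - chicken
  - duck
red_meat_other_than_pork:
  - beef
  - lamb
animal_offal:
  - pork_liver
  - chicken_gizzard
processed_meat:
  - ham
  - beef_jerky
  - luncheon_meat
seafood:
  - fish
  - shrimp
  - crab
eggs:
  - chicken_egg
  - duck_egg
milk:
  - whole_milk
yogurt:
  - plain_yogurt
dairy_products:
  - milk_powder
  - cheese
sauces:
  - catsup
  - soy_sauce_dish
ssb:
  - cola
  - sweetened_fruit_drink
candy_sugar:
  - hard_candy
  - white_sugar
dessert:
  - cake
  - ice_cream
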