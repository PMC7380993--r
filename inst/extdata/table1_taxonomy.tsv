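category	subcategory	keyword	aliases	ingredients
fruit	berry	wildberry		
fruit	berry	currant		
fruit	berry	blackcurrant	black currant	
fruit	berry	blackberry		
fruit	berry	grape		
fruit	berry	raspberry		
fruit	berry	blueberry		
fruit	berry	strawberry		
fruit	tropical	mango		
fruit	tropical	lychee		
fruit	tropical	guava		
fruit	tropical	passion fruit	passionfruit	
fruit	tropical	pineapple		
fruit	citrus	grapefruit		
fruit	citrus	lime		
fruit	citrus	orange		
fruit	citrus	lemon		
fruit	melon	cantaloupe		
fruit	melon	honeydew		
fruit	melon	melon		
fruit	melon	watermelon		
fruit	mixed fruits	mango apricot		
fruit	mixed fruits	apple melon		
fruit	mixed fruits	nana berry		
fruit	others	pomelo		
fruit	others	papaya		
fruit	others	apricot		
fruit	others	dragon fruit	dragonfruit	
fruit	others	pomegranate		
fruit	others	cucumber		
fruit	others	kiwi		
fruit	others	pear		
fruit	others	cherry		
fruit	others	peach		
fruit	others	coconut		
fruit	others	banana		
fruit	others	apple		
sweets	dessert	mochi		
sweets	dessert	pie		
sweets	dessert	waffle		
sweets	dessert	donut	doughnut	
sweets	dessert	cake		
sweets	dessert	s'more	smore	
sweets	dessert	muffin		
sweets	dessert	ice cream		
sweets	dessert	cream		
sweets	dessert	custard		
sweets	dessert	macaron		
sweets	dessert	granola		
sweets	dessert	pastry		
sweets	dessert	meringue		
sweets	dessert	bread		
sweets	dessert	cheesecake		
sweets	dessert	cookie		
sweets	candy	lollypop	lollipop	
sweets	candy	jelly bean	jellybean	
sweets	candy	gummy bear		
sweets	candy	cotton candy		
sweets	candy	marshmallow		
sweets	candy	bubble gum	bubblegum	
sweets	candy	chocolate		
sweets	others	cereal		
sweets	others	honey		
sweets	others	caramel		
beverage	coffee	latte		
beverage	coffee	mocha		
beverage	coffee	cappuccino		
beverage	coffee	espresso		
beverage	coffee	coffee		
beverage	tea	chai		
beverage	tea	tea		
beverage	juice	limeade		
beverage	juice	lemonade		
beverage	juice	apple juice		
beverage	milk	yogurt	yoghurt	
beverage	milk	milkshake		
beverage	milk	milk		
beverage	soft drinks	cola		
beverage	soft drinks	coke		
beverage	soft drinks	soda		
beverage	others	energy drink		
beverage	others	smoothie		
tobacco	tobacco	classic tobacco		
tobacco	tobacco	virginia tobacco		
tobacco	tobacco	cigar		
menthol_or_mint	menthol	menthol		
menthol_or_mint	mint	mint		
menthol_or_mint	mint	peppermint		
menthol_or_mint	mint	spearmint		
mixed	mixed	fruit + mint		fruit,menthol_or_mint
mixed	mixed	fruit + sweets		fruit,sweets
mixed	mixed	fruit + beverage		fruit,beverage
mixed	mixed	sweets + other		sweets,others
mixed	mixed	sweets + mint		sweets,menthol_or_mint
mixed	mixed	sweets + tobacco		sweets,tobacco
mixed	mixed	fruit + tobacco		fruit,tobacco
others	alcohol	margarita		
others	alcohol	whiskey	whisky	
others	alcohol	rum		
others	alcohol	bourbon		
others	alcohol	cocktail		
others	nuts	walnut		
others	nuts	pecan		
others	nuts	pistachio		
others	nuts	hazelnut		
others	nuts	almond		
others	nuts	peanut butter		
others	spice	vanilla		
others	spice	cinnamon		
others	others	pure vg		
others	others	pure pg		
others	others	pg/vg		
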